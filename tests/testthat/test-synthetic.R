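# Ground-truth generator: templates, timecourses, rendering, study I/O.

test_that("templates are deterministic, bounded and peak at their centers", {
  cfg <- synth_config_small(seed = 4)
  t1 <- make_network_templates(cfg)
  t2 <- make_network_templates(cfg)
  expect_identical(t1, t2)
  expect_length(t1, 8L)
  for (tpl in t1) {
    expect_equal(tpl$map[tpl$center[1], tpl$center[2], tpl$center[3]], 1)
    expect_equal(max(tpl$map), 1)
    expect_true(all(tpl$map >= 0 & tpl$map <= 1))
  }

  # single-network degenerate case
  c1 <- synth_config_small(n_networks = 1, seed = 2)
  tpl <- make_network_templates(c1)[[1]]
  expect_equal(tpl$map[tpl$center[1], tpl$center[2], tpl$center[3]], 1)
})

test_that("within-domain template centers are closer than cross-domain ones", {
  cfg <- synth_config_small(seed = 4)
  tpls <- make_network_templates(cfg)
  centers <- t(sapply(tpls, `[[`, "center"))
  doms <- sapply(tpls, `[[`, "domain")
  D <- as.matrix(dist(centers))
  same <- outer(doms, doms, `==`) & upper.tri(D)
  cross <- !outer(doms, doms, `==`) & upper.tri(D)
  expect_true(mean(D[same]) < mean(D[cross]))
})

test_that("grid too small for the networks fails naming the constraint", {
  expect_error(make_network_templates(
    synth_config(grid_dims = c(8, 30, 30), n_networks = 8)), "too small")
})

test_that("timecourse correlation structure hits the configured margin", {
  # 4 networks in 2 domains; empirical within-minus-cross correlation over
  # repeated subjects should approach the margin
  diffs <- sapply(1:60, function(i) {
    cfg <- synth_config(grid_dims = c(24, 28, 24), n_networks = 4,
                        domains = c("SM", "SM", "VI", "VI"),
                        n_timepoints = 600, coupling_within = 0.4, seed = i)
    tc <- simulate_timecourses(cfg, "control", 1)
    R <- cor(tc)
    within <- mean(c(R[1, 2], R[3, 4]))
    cross <- mean(R[1:2, 3:4])
    within - cross
  })
  # sample correlations of strongly autocorrelated series are biased low by
  # ~rho(1-rho^2)/(2 n_eff); allow for that on top of Monte-Carlo error
  expect_lt(abs(mean(diffs) - 0.4), 0.05)
})

test_that("timecourses are seeded, shaped, and validate coupling targets", {
  cfg <- synth_config_small(seed = 9, n_timepoints = 2)
  tc <- simulate_timecourses(cfg, "control", 3)
  expect_equal(dim(tc), c(2L, 8L))
  expect_true(all(is.finite(tc)))
  expect_identical(tc, simulate_timecourses(cfg, "control", 3))
  expect_false(identical(tc, simulate_timecourses(cfg, "control", 4)))

  # an over-large coupling shift is rejected as an invalid correlation target
  bad <- synth_config_small(
    coupling_effect = data.frame(domain_a = "SM", domain_b = "DMN", delta = 0.9),
    coupling_within = 0.45)
  expect_error(simulate_timecourses(bad, "patient", 1), "outside \\(-1, 1\\)")

  # a null coupling effect leaves the patient construction identical
  null_eff <- synth_config_small(
    coupling_effect = data.frame(domain_a = "SM", domain_b = "DMN", delta = 0))
  base <- synth_config_small()
  expect_identical(simulate_timecourses(null_eff, "patient", 2),
                   simulate_timecourses(base, "patient", 2))
})

test_that("rendering honours the additive model and degenerate settings", {
  # no jitter, no noise, constant amplitude: every timepoint identical
  cfg <- synth_config(grid_dims = c(14, 14, 14), n_networks = 2,
                      n_timepoints = 4, jitter_sd = 0, noise_sd = 0,
                      amp_gain = 0, seed = 5)
  r <- render_subject(make_network_templates(cfg), cfg, "control", 1)
  for (t in 2:4) expect_equal(r$volume[, , , t], r$volume[, , , 1])

  # zero noise: volume is exactly the sum of the true maps
  cfg2 <- synth_config(grid_dims = c(14, 14, 14), n_networks = 3,
                       n_timepoints = 3, noise_sd = 0, seed = 6)
  r2 <- render_subject(make_network_templates(cfg2), cfg2, "control", 2)
  expect_equal(r2$volume, Reduce(`+`, r2$truth$score_maps), tolerance = 1e-12)

  # score maps bounded in [0, 1]; volume finite; timecourses finite
  for (m in r2$truth$score_maps) expect_true(all(m >= 0 & m <= 1))
  expect_true(all(is.finite(r2$volume)))
  expect_true(all(is.finite(r2$truth$timecourses)))
})

test_that("studies are reproducible and NIfTI output round-trips", {
  cfg <- synth_config(grid_dims = c(14, 14, 14), n_networks = 2,
                      n_timepoints = 3, n_control = 2, n_patient = 3, seed = 8)
  dir <- withr::local_tempdir()
  manifest <- make_group_study(cfg, dir)

  expect_equal(nrow(manifest), 5L)
  expect_equal(sum(manifest$group == "patient"), 3L)
  expect_true(all(file.exists(manifest$path)))
  on_disk <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(names(on_disk), c("subject_id", "group", "path"))

  study <- attr(manifest, "study")
  reread <- RNifti::readNifti(manifest$path[1])
  expect_equal(as.array(reread), study$subjects[[1]]$volume, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(RNifti::pixdim(reread)[1:3], c(3, 3, 3))

  # full determinism: an independent simulation of the same config matches
  study2 <- simulate_study(cfg)
  expect_identical(study$subjects[[3]]$volume, study2$subjects[[3]]$volume)
  expect_identical(study$subjects[[5]]$truth$score_maps,
                   study2$subjects[[5]]$truth$score_maps)

  # byte-identical NIfTI payloads when the same study is written twice
  dir2 <- withr::local_tempdir()
  make_group_study(cfg, dir2)
  f1 <- manifest$path[2]
  f2 <- file.path(dir2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("patient effects act as configured", {
  # amplitude effect raises patient score-map amplitude on the target network
  cfg <- synth_config(grid_dims = c(16, 16, 16), n_networks = 2,
                      n_timepoints = 20, amplitude_effect = c(1.5, 1),
                      noise_sd = 0, seed = 12)
  tpl <- make_network_templates(cfg)
  rc <- render_subject(tpl, cfg, "control", 1)
  rp <- render_subject(tpl, cfg, "patient", 1)
  expect_gt(mean(rp$truth$score_maps[[1]]), mean(rc$truth$score_maps[[1]]))

  # reduced deviation effect lowers patient temporal deviation
  cfgd <- synth_config(grid_dims = c(16, 16, 16), n_networks = 1,
                       n_timepoints = 30, deviation_effect = 0.2,
                       amp_gain = 0, noise_sd = 0, jitter_sd = 1, seed = 13)
  tpld <- make_network_templates(cfgd)
  tds <- sapply(1:6, function(i) c(
    control = sum(unclass(temporal_deviation(
      render_subject(tpld, cfgd, "control", i)$truth$score_maps[[1]]))),
    patient = sum(unclass(temporal_deviation(
      render_subject(tpld, cfgd, "patient", i)$truth$score_maps[[1]])))))
  expect_gt(mean(tds["control", ]), mean(tds["patient", ]))
})
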