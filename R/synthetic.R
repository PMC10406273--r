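DOMAIN_NAMES <- c("SM", "DMN", "AU", "CC", "VI", "SC", "CB")

# Network-per-domain split used for the 53-network default, mirroring the
# published template's domain sizes (SC 5, AU 2, SM 9, VI 9, CC 17, DMN 7,
# CB 4).
default_domains <- function(K) {
  if (K == 53) {
    counts <- c(SM = 9, DMN = 7, AU = 2, CC = 17, VI = 9, SC = 5, CB = 4)
  } else {
    D <- min(K, 7L)
    base <- K %/% D
    counts <- rep(base, D) + c(rep(1L, K %% D), rep(0L, D - K %% D))
    names(counts) <- DOMAIN_NAMES[seq_len(D)]
  }
  rep(names(counts), counts)
}

#' Configuration of a synthetic fMRI study
#'
#' Defines a seeded, fully reproducible study of "preprocessed-looking" 4D
#' fMRI volumes: K overlapping networks (anisotropic Gaussian blobs) grouped
#' into up to 7 named domains, domain-structured low-pass timecourses,
#' smooth voxel-level spatial dynamics (an Ornstein-Uhlenbeck-style random
#' walk on each blob's center and log-width), additive i.i.d. Gaussian
#' noise, and configurable control-vs-patient effects:
#'
#' * `amplitude_effect` — per-network multiplicative scaling of the patient
#'   group's network amplitude (1 = no effect);
#' * `deviation_effect` — per-network scaling of the patient group's spatial
#'   jitter (< 1 means patients' networks move less, i.e. reduced spatial
#'   dynamics);
#' * `coupling_effect` — additive shifts of between-domain timecourse
#'   correlation for the patient group, given as a data frame with columns
#'   `domain_a`, `domain_b`, `delta`.
#'
#' The same seed always reproduces the identical study.
#'
#' @param grid_dims 3 positive integers (voxels); default the 3 mm
#'   standard-space grid `c(53, 63, 52)`.
#' @param n_networks Number of networks K (default 53).
#' @param domains Character vector of length K assigning each network to one
#'   of the 7 domain labels; default splits networks over the domains.
#' @param n_timepoints Scan length T (default 150).
#' @param n_control,n_patient Subject counts (default 20 each).
#' @param noise_sd Standard deviation of the additive voxel noise.
#' @param amplitude_effect Scalar or length-K vector (patients).
#' @param deviation_effect Scalar or length-K vector (patients).
#' @param coupling_effect `NULL` or data frame (`domain_a`, `domain_b`,
#'   `delta`).
#' @param jitter_sd Stationary standard deviation, in voxels, of the blob
#'   center random walk (spatial-dynamics magnitude).
#' @param lobe2_amp Relative amplitude of each network's secondary lobe
#'   (0 disables it, giving single-blob networks).
#' @param coupling_within Target within-domain timecourse correlation; also
#'   the margin by which within-domain exceeds cross-domain correlation.
#' @param amp_base,amp_gain Baseline and gain mapping a unit-variance
#'   timecourse to the amplitude of a network's score map in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `synth_config` object.
#' @export
synth_config <- function(grid_dims = c(53L, 63L, 52L), n_networks = 53L,
                         domains = NULL, n_timepoints = 150L,
                         n_control = 20L, n_patient = 20L, noise_sd = 0.05,
                         amplitude_effect = 1, deviation_effect = 1,
                         coupling_effect = NULL, jitter_sd = 0.5,
                         lobe2_amp = 0.6, coupling_within = 0.45,
                         amp_base = 0.45, amp_gain = 0.12, seed = 1L) {
  stopifnot(length(grid_dims) == 3, all(vapply(grid_dims, is_count, logical(1))),
            is_count(n_networks), is_count(n_timepoints),
            is_count(n_control), is_count(n_patient),
            noise_sd >= 0, jitter_sd >= 0, lobe2_amp >= 0, lobe2_amp < 1,
            coupling_within > 0, coupling_within < 1,
            amp_base >= 0, amp_gain >= 0, amp_base + 3 * amp_gain <= 1.2)
  K <- as.integer(n_networks)
  domains <- domains %||% default_domains(K)
  if (length(domains) != K || !all(domains %in% DOMAIN_NAMES)) {
    abort("domains must assign each of the K networks one of the 7 domain labels")
  }
  amplitude_effect <- rep_len(amplitude_effect, K)
  deviation_effect <- rep_len(deviation_effect, K)
  stopifnot(all(amplitude_effect > 0), all(deviation_effect >= 0))
  if (!is.null(coupling_effect)) {
    coupling_effect <- as.data.frame(coupling_effect)
    stopifnot(all(c("domain_a", "domain_b", "delta") %in% names(coupling_effect)))
    bad <- !(coupling_effect$domain_a %in% domains &
               coupling_effect$domain_b %in% domains)
    if (any(bad)) abort("coupling_effect refers to domains with no networks")
  }
  structure(
    list(grid_dims = as.integer(grid_dims), n_networks = K, domains = domains,
         n_timepoints = as.integer(n_timepoints),
         n_control = as.integer(n_control), n_patient = as.integer(n_patient),
         noise_sd = noise_sd, amplitude_effect = amplitude_effect,
         deviation_effect = deviation_effect, coupling_effect = coupling_effect,
         jitter_sd = jitter_sd, lobe2_amp = lobe2_amp,
         coupling_within = coupling_within,
         amp_base = amp_base, amp_gain = amp_gain, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Small-grid preset of [synth_config()]
#'
#' A reduced study (24 x 28 x 24 voxels, 8 networks, 60 timepoints) used as
#' the routine test fixture; the full-size grid is reserved for integration
#' runs.
#'
#' @param ... Overrides passed to [synth_config()].
#' @export
synth_config_small <- function(...) {
  args <- list(grid_dims = c(24L, 28L, 24L), n_networks = 8L,
               n_timepoints = 60L)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

#' Construct the K network templates
#'
#' Places one two-lobed anisotropic Gaussian blob per network on the grid,
#' deterministically given the config seed. Domains get well-separated
#' anchor locations (greedy max-min placement over a seeded candidate set);
#' each network's primary lobe is a small perturbation of its domain's
#' anchor, so networks in the same domain are closer to each other than to
#' networks of other domains — the source of the domain-block structure in
#' connectivity matrices. A weaker secondary lobe (relative amplitude
#' `lobe2_amp`) sits near the *next* domain's anchor, making networks of
#' neighbouring domains spatially overlapping, as real network templates
#' are; without cross-domain overlap, map-based connectivity would be
#' blind to temporal coupling between domains. Each template's map attains
#' its maximum of 1 at the (integer) primary center voxel.
#'
#' @param cfg A [synth_config()].
#' @return A list of `K` templates, each
#'   `list(network_id, domain, center, centers, widths, widths2, map)`
#'   where `center` is the primary lobe center and `centers` lists both
#'   lobes; class `network_templates`.
#' @export
make_network_templates <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  g <- cfg$grid_dims
  K <- cfg$n_networks
  if (prod(g) < 125 * length(unique(cfg$domains)) || any(g < 12)) {
    abort(sprintf(
      "grid %s is too small to place %d networks in %d domains: need every dimension >= 12 and >= 125 voxels per domain",
      fmt_dims(g), K, length(unique(cfg$domains))))
  }
  margin <- pmax(4L, round(g * 0.15))
  active <- unique(cfg$domains)
  with_seed(derive_seed(cfg$seed, 1L), {
    # candidate anchor pool, greedy max-min selection
    n_cand <- 256L
    cand <- cbind(
      sample(margin[1]:(g[1] - margin[1] + 1L), n_cand, replace = TRUE),
      sample(margin[2]:(g[2] - margin[2] + 1L), n_cand, replace = TRUE),
      sample(margin[3]:(g[3] - margin[3] + 1L), n_cand, replace = TRUE))
    anchors <- matrix(0L, length(active), 3)
    anchors[1, ] <- cand[1, ]
    if (length(active) > 1) {
      for (d in 2:length(active)) {
        dists <- apply(cand, 1, function(p) {
          min(sqrt(rowSums((anchors[seq_len(d - 1L), , drop = FALSE] -
                              matrix(p, d - 1L, 3, byrow = TRUE))^2)))
        })
        anchors[d, ] <- cand[which.max(dists), ]
      }
    }
    rownames(anchors) <- active
    w_hi <- 2 + min(g) / 12
    lobe2_amp <- cfg$lobe2_amp
    templates <- lapply(seq_len(K), function(k) {
      dom <- cfg$domains[k]
      nxt <- active[match(dom, active) %% length(active) + 1L]
      center <- pmin(pmax(anchors[dom, ] + round(rnorm(3, sd = 1.5)), margin),
                     g - margin + 1L)
      center2 <- pmin(pmax(anchors[nxt, ] + round(rnorm(3, sd = 1.5)), margin),
                      g - margin + 1L)
      widths <- runif(3, 2, w_hi)
      widths2 <- runif(3, 2, w_hi)
      map <- pmax(gaussian_blob(g, center, widths),
                  lobe2_amp * gaussian_blob(g, center2, widths2))
      list(network_id = k, domain = dom, center = as.integer(center),
           centers = list(as.integer(center), as.integer(center2)),
           widths = widths, widths2 = widths2, lobe2_amp = lobe2_amp,
           map = map)
    })
  })
  structure(templates, class = "network_templates", grid_dims = g)
}

# Separable axis-aligned Gaussian on the voxel grid; value 1 at `center`
# when `center` is on-grid.
gaussian_blob <- function(grid_dims, center, widths) {
  gx <- exp(-0.5 * ((seq_len(grid_dims[1]) - center[1]) / widths[1])^2)
  gy <- exp(-0.5 * ((seq_len(grid_dims[2]) - center[2]) / widths[2])^2)
  gz <- exp(-0.5 * ((seq_len(grid_dims[3]) - center[3]) / widths[3])^2)
  array(outer(outer(gx, gy), gz), dim = grid_dims)
}

# Domain-level latent correlation matrix for one group. Cross-domain
# correlations are 0 for controls; `coupling_effect` raises the patient
# group's network-level correlation between two domains to `delta`, which
# requires a latent correlation of delta / coupling_within.
domain_corr <- function(cfg, group) {
  active <- unique(cfg$domains)
  R <- diag(length(active))
  dimnames(R) <- list(active, active)
  if (group == "patient" && !is.null(cfg$coupling_effect)) {
    for (i in seq_len(nrow(cfg$coupling_effect))) {
      row <- cfg$coupling_effect[i, ]
      r <- row$delta / cfg$coupling_within
      if (abs(row$delta) >= 1 || abs(r) >= 1) {
        abort(sprintf(
          "coupling_effect delta %.3f for (%s, %s) implies a target correlation outside (-1, 1)",
          row$delta, row$domain_a, row$domain_b))
      }
      R[row$domain_a, row$domain_b] <- r
      R[row$domain_b, row$domain_a] <- r
    }
    ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
    if (!ok) abort("coupling_effect produces an invalid (non positive-definite) correlation structure")
  }
  R
}

#' Simulate network timecourses for one subject
#'
#' Draws a T x K matrix of smooth (AR(1), low-pass) unit-variance signals:
#' each network mixes a latent signal shared by its domain with a private
#' component, so that within-domain pairs correlate at `coupling_within`
#' while cross-domain pairs are uncorrelated for controls. For patients,
#' `coupling_effect` shifts the specified domain-pair correlations by
#' correlating the domain latents. Deterministic given the config seed,
#' group and subject index.
#'
#' @param cfg A [synth_config()].
#' @param group `"control"` or `"patient"`.
#' @param subject_index Positive integer.
#' @return A `n_timepoints` x `n_networks` matrix.
#' @export
simulate_timecourses <- function(cfg, group = c("control", "patient"),
                                 subject_index = 1L) {
  stopifnot(inherits(cfg, "synth_config"), cfg$n_timepoints >= 2)
  group <- match.arg(group)
  R <- domain_corr(cfg, group)
  active <- rownames(R)
  lambda <- cfg$coupling_within
  with_seed(derive_seed(cfg$seed, match(group, c("control", "patient")),
                        subject_index, 1L), {
    L <- ar1_series(cfg$n_timepoints, length(active)) %*% chol(R)
    colnames(L) <- active
    E <- ar1_series(cfg$n_timepoints, cfg$n_networks)
    sqrt(lambda) * L[, cfg$domains, drop = FALSE] + sqrt(1 - lambda) * E
  })
}

# Ornstein-Uhlenbeck-style smooth random walks for one network's spatial
# dynamics: 3 center offsets (stationary sd = sd_center voxels) and 3
# log-width offsets (stationary sd = sd_logw).
ou_paths <- function(T, sd_center, sd_logw, rho = 0.9) {
  list(center = ar1_series(T, 3, phi = rho) * sd_center,
       logw = ar1_series(T, 3, phi = rho) * sd_logw)
}

#' Render one subject's 4D fMRI volume and ground truth
#'
#' At each timepoint the true score map of network k is its template with
#' center and log-width perturbed by a smooth random walk of scale
#' `jitter_sd` (scaled by `deviation_effect` for patients) and amplitude
#' modulated by the network's timecourse (mapped into `[0, 1]`, and
#' multiplied by `amplitude_effect` for patients). The fMRI volume is the
#' sum of the network maps plus i.i.d. Gaussian noise.
#'
#' @param templates A [make_network_templates()] result for the same config.
#' @param cfg The [synth_config()].
#' @param group `"control"` or `"patient"`.
#' @param subject_index Positive integer.
#' @param keep_truth Return the per-network true score maps (memory-heavy
#'   for large grids).
#' @param render_volume Render the noisy fMRI volume (set `FALSE` when only
#'   ground-truth maps are needed).
#' @return `list(volume, truth)` where `truth` is
#'   `list(subject_id, group, score_maps, timecourses)`.
#' @export
render_subject <- function(templates, cfg, group = c("control", "patient"),
                           subject_index = 1L, keep_truth = TRUE,
                           render_volume = TRUE) {
  stopifnot(inherits(templates, "network_templates"), inherits(cfg, "synth_config"))
  group <- match.arg(group)
  g <- cfg$grid_dims
  K <- cfg$n_networks
  T <- cfg$n_timepoints
  tc <- simulate_timecourses(cfg, group, subject_index)

  amp <- pmin(pmax(cfg$amp_base + cfg$amp_gain * tc, 0), 1)
  if (group == "patient") {
    amp <- pmin(sweep(amp, 2, cfg$amplitude_effect, `*`), 1)
  }

  gcode <- match(group, c("control", "patient"))
  jit <- with_seed(derive_seed(cfg$seed, gcode, subject_index, 2L), {
    lapply(seq_len(K), function(k) {
      s <- cfg$jitter_sd * if (group == "patient") cfg$deviation_effect[k] else 1
      ou_paths(T, sd_center = s, sd_logw = 0.1 * s)
    })
  })

  volume <- if (render_volume) array(0, dim = c(g, T)) else NULL
  score_maps <- if (keep_truth) {
    lapply(seq_len(K), function(k) array(0, dim = c(g, T)))
  }
  for (t in seq_len(T)) {
    for (k in seq_len(K)) {
      tpl <- templates[[k]]
      shape <- gaussian_blob(g, tpl$center + jit[[k]]$center[t, ],
                             tpl$widths * exp(jit[[k]]$logw[t, ]))
      if (!is.null(tpl$centers) && length(tpl$centers) > 1) {
        shape <- pmax(shape, tpl$lobe2_amp * gaussian_blob(
          g, tpl$centers[[2]] + jit[[k]]$center[t, ],
          tpl$widths2 * exp(jit[[k]]$logw[t, ])))
      }
      m <- amp[t, k] * shape
      if (keep_truth) score_maps[[k]][, , , t] <- m
      if (render_volume) volume[, , , t] <- volume[, , , t] + m
    }
  }
  if (render_volume && cfg$noise_sd > 0) {
    noise <- with_seed(derive_seed(cfg$seed, gcode, subject_index, 3L),
                       rnorm(length(volume), sd = cfg$noise_sd))
    volume <- volume + noise
  }
  id <- sprintf("sub-%s%03d", if (group == "control") "C" else "P", subject_index)
  list(volume = volume,
       truth = list(subject_id = id, group = group, score_maps = score_maps,
                    timecourses = tc))
}

#' Simulate a whole study in memory
#'
#' Renders all control and patient subjects of a config, returning the
#' volumes, ground truth and a manifest tibble.
#'
#' @param cfg A [synth_config()].
#' @param keep_truth,render_volume Passed to [render_subject()].
#' @return A `synth_study`: `list(cfg, templates, subjects, manifest)`.
#' @export
simulate_study <- function(cfg, keep_truth = TRUE, render_volume = TRUE) {
  templates <- make_network_templates(cfg)
  spec <- dplyr::bind_rows(
    tibble(group = "control", index = seq_len(cfg$n_control)),
    tibble(group = "patient", index = seq_len(cfg$n_patient)))
  subjects <- purrr::pmap(spec, function(group, index) {
    r <- render_subject(templates, cfg, group, index,
                        keep_truth = keep_truth, render_volume = render_volume)
    list(subject_id = r$truth$subject_id, group = group,
         volume = r$volume, truth = r$truth)
  })
  manifest <- tibble(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = vapply(subjects, `[[`, "", "group"),
    path = NA_character_)
  structure(list(cfg = cfg, templates = templates, subjects = subjects,
                 manifest = manifest),
            class = "synth_study")
}

#' Write a synthetic study to disk
#'
#' Writes each subject's 4D fMRI volume (NIfTI-1, 3 mm voxels), the
#' per-network ground-truth score maps, the timecourse matrix (CSV) and a
#' manifest CSV with header `subject_id,group,path`.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param keep_truth Also write ground-truth maps.
#' @return The manifest tibble (invisibly carries the in-memory study as
#'   attribute `study`).
#' @export
make_group_study <- function(cfg, dir, keep_truth = TRUE) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(sprintf("cannot create study directory '%s'", dir))
  }
  study <- simulate_study(cfg, keep_truth = keep_truth)
  manifest <- study$manifest
  for (i in seq_along(study$subjects)) {
    s <- study$subjects[[i]]
    path <- file.path(dir, paste0(s$subject_id, "_fmri.nii.gz"))
    write_nifti_vol(s$volume, path)
    manifest$path[i] <- path
    if (keep_truth) {
      for (k in seq_along(s$truth$score_maps)) {
        write_nifti_vol(s$truth$score_maps[[k]],
                        file.path(dir, sprintf("%s_net%02d_truth.nii.gz",
                                               s$subject_id, k)))
      }
      utils::write.csv(as.data.frame(s$truth$timecourses),
                       file.path(dir, paste0(s$subject_id, "_timecourses.csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  study$manifest <- manifest
  attr(manifest, "study") <- study
  invisible(manifest)
}

write_nifti_vol <- function(arr, path, voxel_mm = 3) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3), rep(2, nd - 3))
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("failed to write NIfTI '%s': %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Brain mask of a synthetic study
#'
#' Union of the template supports (template value above `level`), the region
#' where networks actually live; correlating full-grid background would
#' dilute connectivity estimates.
#'
#' @param templates A [make_network_templates()] result.
#' @param level Support threshold on the template maps.
#' @return A logical 3D array.
#' @export
study_mask <- function(templates, level = 0.05) {
  Reduce(`|`, lapply(templates, function(t) t$map > level))
}
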