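# Voxel-wise summary maps and group inference, checked against brute-force
# loop oracles.

loop_time_mean <- function(w) {
  d <- dim(w)
  out <- array(0, d[1:3])
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    out[i, j, k] <- mean(w[i, j, k, ])
  }
  out
}

loop_temporal_deviation <- function(w) {
  d <- dim(w)
  out <- array(0, d[1:3])
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    s <- 0
    for (t in 1:(d[4] - 1)) s <- s + abs(w[i, j, k, t + 1] - w[i, j, k, t])
    out[i, j, k] <- s
  }
  out
}

test_that("time_mean matches the loop oracle and handles edge cases", {
  w <- random_map4d(c(4, 5, 3, 6), seed = 1)
  expect_equal(vals(time_mean(w)), loop_time_mean(w), tolerance = 1e-12)
  expect_equal(attr(time_mean(w), "kind"), "time_mean")

  # mean of the voxel series (0.2, 0.4) is 0.3
  w2 <- array(c(0.2, 0.4), c(1, 1, 1, 2))
  expect_equal(as.numeric(time_mean(w2)), 0.3)

  # T = 1 is the identity; constant-in-time maps return the constant frame
  w1 <- random_map4d(c(3, 3, 3, 1), seed = 2)
  expect_equal(vals(time_mean(w1)), w1[, , , 1])
  wc <- array(rep(w1[, , , 1], 4), c(3, 3, 3, 4))
  expect_equal(vals(time_mean(wc)), w1[, , , 1])
})

test_that("temporal_deviation matches the loop oracle and is zero iff constant", {
  w <- random_map4d(c(4, 4, 4, 7), seed = 3)
  td <- temporal_deviation(w)
  expect_equal(vals(td), loop_temporal_deviation(w), tolerance = 1e-12)
  expect_true(all(td >= 0))

  # hand-computed series: |3-1| + |2-3| = 3
  w2 <- array(c(1, 3, 2), c(1, 1, 1, 3))
  expect_equal(as.numeric(temporal_deviation(w2)), 3)

  # monotone series telescope to last - first
  mono <- array(cumsum(runif(5)), c(1, 1, 1, 5))
  expect_equal(as.numeric(temporal_deviation(mono)),
               mono[1, 1, 1, 5] - mono[1, 1, 1, 1])

  # zero exactly at time-constant voxels, nonzero elsewhere
  w[2, 2, 2, ] <- 0.7
  td <- vals(temporal_deviation(w))
  expect_equal(td[2, 2, 2], 0)
  expect_equal(sum(td == 0), 1L)
  expect_true(all(td[td != 0] > 0))

  expect_error(temporal_deviation(random_map4d(c(2, 2, 2, 1))), "2 timepoints")
})

test_that("subject_mean averages voxel-wise, promotes kind, and is symmetric", {
  a <- time_mean(random_map4d(c(3, 4, 2, 5), seed = 4))
  b <- time_mean(random_map4d(c(3, 4, 2, 5), seed = 5))
  m <- subject_mean(list(a, b))
  expect_equal(vals(m), (vals(a) + vals(b)) / 2)
  expect_equal(attr(m, "kind"), "group_mean")
  expect_equal(attr(subject_mean(list(temporal_deviation(
    random_map4d(c(2, 2, 2, 3))))), "kind"), "group_deviation")
  # single subject: identity; permutation invariance
  expect_equal(vals(subject_mean(list(a))), vals(a))
  expect_equal(subject_mean(list(a, b)), subject_mean(list(b, a)))
  expect_error(subject_mean(list(a, temporal_deviation(random_map4d(c(3, 4, 2, 5))))),
               "mixed kinds")
})

test_that("time_mean and subject_mean commute", {
  ws <- lapply(1:3, function(i) random_map4d(c(3, 3, 3, 4), seed = i))
  a <- subject_mean(lapply(ws, time_mean))
  b <- time_mean(array(Reduce(`+`, ws) / 3, c(3, 3, 3, 4)))
  expect_equal(vals(a), vals(b), tolerance = 1e-12)
})

test_that("voxelwise Welch t matches hand evaluation and t.test", {
  # the worked example: (1,2,3) vs (2,3,4) gives t = -sqrt(3/2)
  gc <- lapply(1:3, function(i) array(i, c(1, 1, 1)))
  gs <- lapply(2:4, function(i) array(i, c(1, 1, 1)))
  res <- voxelwise_ttest(gc, gs)
  expect_equal(as.numeric(res$t), -sqrt(1.5), tolerance = 1e-10)
  expect_equal(as.numeric(res$t), -1.2247449, tolerance = 1e-6)

  # independent route: stats::t.test on random per-voxel data
  set.seed(8)
  gc <- lapply(1:4, function(i) array(rnorm(8), c(2, 2, 2)))
  gs <- lapply(1:5, function(i) array(rnorm(8, 0.5), c(2, 2, 2)))
  res <- voxelwise_ttest(gc, gs)
  for (v in c(1, 5, 8)) {
    ref <- t.test(sapply(gc, `[`, v), sapply(gs, `[`, v))
    expect_equal(vals(res$t)[v], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[v], ref$p.value, tolerance = 1e-10)
    expect_equal(res$df[v], unname(ref$parameter), tolerance = 1e-10)
  }

  # antisymmetry under group swap; sign matches mean difference
  swapped <- voxelwise_ttest(gs, gc)
  expect_equal(vals(swapped$t), -vals(res$t))
  expect_equal(sign(vals(res$t)), sign(res$mean_c - res$mean_s))

  # identical groups: t identically zero
  same <- voxelwise_ttest(gc, gc)
  expect_true(all(vals(same$t) == 0))

  # zero-variance voxels are masked with t = 0, not infinite
  gc0 <- lapply(1:3, function(i) array(1, c(1, 1, 1)))
  gs0 <- lapply(1:3, function(i) array(2, c(1, 1, 1)))
  z <- voxelwise_ttest(gc0, gs0)
  expect_equal(as.numeric(z$t), 0)
  expect_false(any(z$valid))

  expect_error(voxelwise_ttest(gc[1], gs), "length")
})

test_that("difference map is local and antisymmetric", {
  a <- map3d(array(0, c(3, 3, 3)), "group_mean")
  b <- a
  expect_equal(vals(difference_map(a, b)), array(0, c(3, 3, 3)))
  b2 <- vals(b); b2[2, 1, 3] <- 1; b2 <- map3d(b2, "group_mean")
  d <- difference_map(a, b2)
  expect_equal(sum(vals(d) != 0), 1L)
  expect_equal(vals(d)[2, 1, 3], -1)
  expect_equal(vals(difference_map(b2, a)), -vals(d))
  expect_error(difference_map(a, map3d(array(0, c(2, 3, 3)), "group_mean")),
               "grid")
})

test_that("peak selection finds signed argmax voxels and reports absent segments", {
  v <- array(0, c(4, 4, 4))
  v[2, 3, 1] <- 0.9
  v[4, 1, 2] <- -0.4
  sel <- select_peaks(map3d(v, "difference"))
  expect_equal(sel$positive, c(2L, 3L, 1L))
  expect_equal(sel$negative, c(4L, 1L, 2L))

  pos_only <- select_peaks(map3d(abs(v) + 0.1, "difference"))
  expect_null(pos_only$negative)
  expect_false(is.null(pos_only$positive))

  expect_error(select_peaks(map3d(v, "difference"), array(FALSE, c(4, 4, 4))),
               "empty mask")

  # per-subject values gathered at the peaks, grouped
  maps <- tibble::tibble(
    subject_id = c("a", "b"), group = c("control", "patient"),
    map = list(v, v * 2))
  filled <- collect_peak_values(sel, maps)
  expect_equal(nrow(filled$values), 4L)
  expect_equal(filled$values$value[filled$values$peak_sign == "positive"],
               c(0.9, 1.8))
})

test_that("threshold_mask rules are correct and monotone", {
  set.seed(11)
  v <- array(rnorm(1000), c(10, 10, 10))
  expect_true(all(threshold_mask(v, cutoff = 0)))
  # upper 1% of 1000 distinct values keeps 10 voxels
  expect_equal(sum(threshold_mask(v, quantile = 0.99)), 10L)
  # stricter rules give subset masks
  m1 <- threshold_mask(v, cutoff = 0.5)
  m2 <- threshold_mask(v, cutoff = 1.5)
  expect_true(all(m1[m2]))
  q1 <- threshold_mask(v, quantile = 0.8)
  q2 <- threshold_mask(v, quantile = 0.95)
  expect_true(all(q1[q2]))
  expect_error(threshold_mask(v, quantile = 1.2), "quantile")
  expect_error(threshold_mask(v), "exactly one")
})

test_that("tidy and glance on t-test results are well-formed", {
  set.seed(3)
  gc <- lapply(1:3, function(i) array(rnorm(8), c(2, 2, 2)))
  gs <- lapply(1:3, function(i) array(rnorm(8), c(2, 2, 2)))
  res <- voxelwise_ttest(gc, gs)
  td <- tidy(res)
  expect_equal(nrow(td), 8L)
  expect_named(td, c("x", "y", "z", "estimate", "statistic", "p.value", "valid"))
  expect_equal(glance(res)$n_voxels, 8L)
})
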