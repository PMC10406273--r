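# Static and dynamic functional network connectivity, states and occupancy.

# brute-force Pearson correlation by explicit loops
loop_cor <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  sab <- 0; saa <- 0; sbb <- 0
  for (i in seq_len(n)) {
    sab <- sab + (a[i] - ma) * (b[i] - mb)
    saa <- saa + (a[i] - ma)^2
    sbb <- sbb + (b[i] - mb)^2
  }
  sab / sqrt(saa * sbb)
}

test_that("sfnc_pair matches the loop oracle and handles degenerate input", {
  wp <- random_map4d(c(4, 5, 4, 6), seed = 1)
  wq <- random_map4d(c(4, 5, 4, 6), seed = 2)
  expect_equal(sfnc_pair(wp, wq), loop_cor(as.vector(wp), as.vector(wq)),
               tolerance = 1e-10)

  expect_equal(sfnc_pair(wp, wp), 1)
  expect_equal(sfnc_pair(wp, -wp + 3), -1)

  # masked version restricts the flattened vectors
  mask <- array(FALSE, c(4, 5, 4)); mask[1:2, , ] <- TRUE
  idx <- which(mask)
  a <- as.vector(matrix(wp, 80, 6)[idx, ])
  b <- as.vector(matrix(wq, 80, 6)[idx, ])
  expect_equal(sfnc_pair(wp, wq, mask), loop_cor(a, b), tolerance = 1e-10)

  expect_true(is.na(sfnc_pair(array(1, dim(wp)), wq)))
  expect_error(sfnc_pair(wp, wq, array(FALSE, c(4, 5, 4))), "empty mask")
})

test_that("sfnc_matrix is symmetric, unit-diagonal and domain-ordered", {
  maps <- lapply(1:4, function(i) random_map4d(c(4, 4, 4, 5), seed = i))
  R <- sfnc_matrix(maps)
  expect_equal(unclass(R), t(unclass(R)))
  expect_equal(diag(R), setNames(rep(1, 4), rownames(R)))
  expect_true(all(R >= -1 & R <= 1))
  expect_equal(R[1, 2], sfnc_pair(maps[[1]], maps[[2]]), tolerance = 1e-12)

  # K = 2 construction and duplicate maps
  R2 <- sfnc_matrix(maps[1:2])
  expect_equal(R2[1, 2], sfnc_pair(maps[[1]], maps[[2]]), tolerance = 1e-12)
  ones <- sfnc_matrix(list(maps[[1]], maps[[1]], maps[[1]]))
  expect_equal(unclass(ones), matrix(1, 3, 3), ignore_attr = TRUE)

  # domain grouping reorders networks and prefixes labels
  Rd <- sfnc_matrix(maps, domains = c("CB", "SM", "CB", "VI"))
  expect_equal(rownames(Rd), c("SM1", "VI1", "CB1", "CB2"))
  expect_equal(Rd["CB1", "CB2"], R[1, 3], tolerance = 1e-12)
})

test_that("dfnc window bookkeeping follows the count formula", {
  K <- 2
  make_maps <- function(T) lapply(1:K, function(i) random_map4d(c(3, 3, 3, T), seed = i))

  # the reference case: 150 timepoints, window 30, overlap 10 -> 7 windows
  w <- dfnc_windows(make_maps(150), window_spec(30, 10))
  expect_length(w, 7L)

  # single-window limit equals the static matrix over that span
  maps30 <- make_maps(30)
  w1 <- dfnc_windows(maps30, window_spec(30, 10))
  expect_length(w1, 1L)
  expect_equal(unclass(w1[[1]]), unclass(sfnc_matrix(maps30)), ignore_attr = TRUE)

  # maximal overlap: T - L + 1 windows
  wmax <- dfnc_windows(make_maps(12), window_spec(5, 4))
  expect_length(wmax, 12 - 5 + 1)

  # property: floor((T - L) / stride) + 1 for random valid specs,
  # against direct enumeration of window start positions
  set.seed(99)
  for (rep in 1:12) {
    T <- sample(10:40, 1)
    L <- sample(3:min(T, 15), 1)
    ov <- sample(seq_len(L - 1), 1)
    stride <- L - ov
    starts <- seq(1, T, by = stride)
    starts <- starts[starts + L - 1 <= T]
    got <- dfnc_windows(make_maps(T), window_spec(L, ov))
    expect_length(got, floor((T - L) / stride) + 1)
    expect_length(got, length(starts))
  }

  expect_error(dfnc_windows(make_maps(10), window_spec(30, 10)), "10 timepoints")
  expect_error(window_spec(30, 30))
  expect_error(window_spec(30, 0))
})

test_that("k-means states: degenerate k, determinism, elbow and recovery", {
  # two well-separated clusters of synthetic windows in FNC feature space
  set.seed(5)
  base1 <- diag(4); base1[1, 2] <- base1[2, 1] <- 0.8
  base2 <- diag(4); base2[3, 4] <- base2[4, 3] <- -0.7
  noisy <- function(base) {
    m <- base + matrix(rnorm(16, sd = 0.03), 4, 4)
    m <- (m + t(m)) / 2; diag(m) <- 1
    structure(m, class = c("fnc_matrix", "matrix", "array"))
  }
  wins <- c(lapply(1:20, function(i) noisy(base1)),
            lapply(1:20, function(i) noisy(base2)))

  sm <- fit_states(wins, k_range = 1:6, seed = 7)
  expect_equal(sm$k_states, 2L)

  labels <- assign_states(wins, sm)
  truth <- rep(1:2, each = 20)
  # perfect recovery up to label permutation
  expect_true(all(labels[1:20] == labels[1]) && all(labels[21:40] == labels[21]))
  expect_true(labels[1] != labels[21])

  # determinism under the seed
  sm2 <- fit_states(wins, k_range = 1:6, seed = 7)
  expect_identical(sm$centroids, sm2$centroids)

  # k = 1 centroid is the mean of all windows
  sm1 <- fit_states(wins, k_range = 1, seed = 3)
  X <- t(sapply(wins, function(m) m[upper.tri(m)]))
  expect_equal(as.vector(sm1$centroids), colMeans(X), tolerance = 1e-12)

  # inertia is non-increasing in k
  expect_true(all(diff(sm$inertia$inertia) <= 1e-8))

  # assignment is a fixed point and ties go to the lowest state index
  again <- assign_states(wins, sm)
  expect_identical(labels, again)
  tied <- structure(matrix(0.5, 4, 4) + diag(0.5, 4),
                    class = c("fnc_matrix", "matrix", "array"))
  eq <- fit_states(list(tied, tied, tied), k_range = 2, seed = 1)
  expect_equal(assign_states(list(tied), eq), 1L)

  expect_error(fit_states(wins[1:3], k_range = 1:6), "windows")
})

test_that("occupancy ratios count states and sum to one", {
  expect_equal(occupancy_ratio(c(1, 1, 2, 2), 2), c(0.5, 0.5))
  expect_equal(occupancy_ratio(rep(3, 5), 4), c(0, 0, 1, 0))
  set.seed(2)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    lab <- sample(k, 30, replace = TRUE)
    or <- occupancy_ratio(lab, k)
    expect_equal(sum(or), 1)
    expect_true(all(or >= 0))
    # relabelling permutes the components identically
    perm <- sample(k)
    expect_equal(occupancy_ratio(perm[lab], k)[perm], or)
  }
  expect_error(occupancy_ratio(integer(0), 3), "empty")
})

test_that("FNC group test: null gives empty mask, BH set nests in raw set", {
  set.seed(21)
  rand_fnc <- function(jit = 0) {
    m <- diag(4)
    v <- runif(6, -0.3, 0.3) + jit
    m[upper.tri(m)] <- v
    m <- m + t(m) - diag(diag(m))
    diag(m) <- 1
    structure(m, class = c("fnc_matrix", "matrix", "array"))
  }
  g1 <- lapply(1:10, function(i) rand_fnc())
  res_same <- fnc_group_test(g1, g1)
  expect_false(any(res_same$sig))

  g2 <- lapply(1:10, function(i) rand_fnc(jit = 0.1))
  res <- fnc_group_test(g1, g2, q = 0.05)
  ut <- upper.tri(res$p)
  expect_true(all(res$p_adj[ut] >= res$p[ut]))
  expect_true(all(which(res$sig[ut]) %in% which(res$p[ut] < 0.05)))
  expect_equal(res$sig, t(res$sig))
  expect_equal(res$t, -fnc_group_test(g2, g1)$t)
})
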