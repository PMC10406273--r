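# Connectivity states: k-means over vectorized dFNC windows, elbow-chosen k,
# nearest-centroid assignment and occupancy ratios.

# Vectorize a set of FNC matrices into a feature matrix (rows = windows).
# Default features are the upper triangle; optionally the full matrix, and
# optionally z-scored columns.
fnc_features <- function(windows, use_upper = TRUE, zscore = FALSE) {
  if (is.matrix(windows) && !inherits(windows, "fnc_matrix")) {
    X <- windows
  } else {
    if (inherits(windows, "fnc_matrix")) windows <- list(windows)
    X <- t(vapply(windows, function(m) {
      m <- unclass(m)
      if (use_upper) m[upper.tri(m)] else as.vector(m)
    }, numeric(if (use_upper) {
      nrow(windows[[1]]) * (nrow(windows[[1]]) - 1) / 2
    } else {
      length(windows[[1]])
    })))
  }
  if (zscore) {
    s <- apply(X, 2, sd)
    X <- scale(X, scale = ifelse(s > 0, s, 1))
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  X
}

# k-means++ seeding (D^2-weighted), then Lloyd iterations via stats::kmeans.
kmeanspp_fit <- function(X, k, iter_max = 100L) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                         byrow = TRUE))^2))
    }
  }
  fit <- tryCatch(
    suppressWarnings(
      kmeans(X, centers = centers, iter.max = iter_max, algorithm = "Lloyd")),
    error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  # degenerate data (duplicated seeding points): assign to nearest seeded
  # center, ties to the lowest index
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
    outer(rep(1, n), rowSums(centers^2))
  cl <- max.col(-d2, ties.method = "first")
  wss <- sum((X - centers[cl, , drop = FALSE])^2)
  list(centers = centers, cluster = cl, tot.withinss = wss)
}

#' Fit connectivity states by k-means over dFNC windows
#'
#' Clusters all subjects' vectorized FNC windows (upper triangles by
#' default, Euclidean distance, k-means++ initialization with `nstart`
#' seeded restarts) for every candidate number of states, then chooses k by
#' an algorithmic elbow criterion: the candidate with the maximum second
#' difference of the inertia (total within-cluster sum of squares) curve.
#'
#' @param windows A list of `fnc_matrix` windows (possibly nested per
#'   subject), or a precomputed feature matrix (rows = windows).
#' @param k_range Candidate numbers of states (default 1:6).
#' @param seed RNG seed; the fit is deterministic given it.
#' @param nstart Restarts per candidate k (best inertia kept).
#' @param use_upper Use the vectorized upper triangle (otherwise the full
#'   matrix).
#' @param zscore Z-score features before clustering.
#' @return A `state_model`: chosen `k_states`, `centroids` (k x features),
#'   the `inertia` tibble over candidates, matrix size `K`, and the
#'   clustering options.
#' @export
fit_states <- function(windows, k_range = 1:6, seed = 1L, nstart = 10L,
                       use_upper = TRUE, zscore = FALSE) {
  if (is.list(windows) && !inherits(windows, "fnc_matrix") &&
      is.list(windows[[1]]) && !inherits(windows[[1]], "fnc_matrix")) {
    windows <- purrr::flatten(windows)
  }
  Kmat <- if (is.list(windows)) nrow(windows[[1]]) else NA_integer_
  X <- fnc_features(windows, use_upper = use_upper, zscore = zscore)
  if (any(k_range > nrow(X))) {
    abort(sprintf("only %d windows but k up to %d requested",
                  nrow(X), max(k_range)))
  }
  k_range <- sort(unique(as.integer(k_range)))
  fits <- with_seed(seed, {
    lapply(k_range, function(k) {
      best <- NULL
      for (r in seq_len(nstart)) {
        f <- kmeanspp_fit(X, k)
        if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
      }
      best
    })
  })
  inertia <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  chosen_idx <- if (length(k_range) >= 3) {
    interior <- 2:(length(k_range) - 1)
    d2 <- inertia[interior - 1] - 2 * inertia[interior] + inertia[interior + 1]
    interior[which.max(d2)]
  } else {
    which.min(inertia)
  }
  structure(
    list(k_states = k_range[chosen_idx],
         centroids = fits[[chosen_idx]]$centers,
         inertia = tibble(k = k_range, inertia = inertia),
         K = Kmat, use_upper = use_upper, zscore = zscore,
         seed = as.integer(seed)),
    class = "state_model"
  )
}

#' Assign windows to their nearest connectivity state
#'
#' Euclidean nearest-centroid labels; exact ties resolve to the lowest
#' state index.
#'
#' @param windows As in [fit_states()].
#' @param model A `state_model`.
#' @return Integer label vector in `1..k_states`.
#' @export
assign_states <- function(windows, model) {
  stopifnot(inherits(model, "state_model"))
  X <- fnc_features(windows, use_upper = model$use_upper,
                    zscore = model$zscore)
  if (ncol(X) != ncol(model$centroids)) {
    abort(sprintf("feature dimension %d does not match centroids (%d)",
                  ncol(X), ncol(model$centroids)))
  }
  d2 <- outer(rowSums(X^2), rep(1, nrow(model$centroids))) -
    2 * X %*% t(model$centroids) +
    outer(rep(1, nrow(X)), rowSums(model$centroids^2))
  max.col(-d2, ties.method = "first")
}

#' Occupancy ratio of connectivity states
#'
#' Fraction of a subject's windows spent in each state; components are
#' nonnegative and sum to 1.
#'
#' @param labels Integer labels in `1..k`.
#' @param k Number of states.
#' @return Numeric vector of length `k`.
#' @export
occupancy_ratio <- function(labels, k) {
  if (length(labels) == 0) abort("empty label sequence")
  stopifnot(is_count(k), all(labels >= 1), all(labels <= k))
  tabulate(labels, nbins = k) / length(labels)
}

#' @export
#' @method tidy state_model
tidy.state_model <- function(x, ...) {
  cent <- x$centroids
  tibble(state = rep(seq_len(nrow(cent)), each = ncol(cent)),
         feature = rep(seq_len(ncol(cent)), times = nrow(cent)),
         value = as.vector(t(cent)))
}

#' @export
#' @method glance state_model
glance.state_model <- function(x, ...) {
  tibble(k_states = x$k_states,
         inertia = x$inertia$inertia[match(x$k_states, x$inertia$k)],
         n_candidates = nrow(x$inertia), seed = x$seed)
}

#' @export
#' @method autoplot state_model
autoplot.state_model <- function(object, ...) {
  if (is.null(object$K) || is.na(object$K) || !object$use_upper) {
    long <- tidy(object)
    return(ggplot2::ggplot(long, ggplot2::aes(x = .data$feature,
                                              y = .data$value)) +
             ggplot2::geom_col() +
             ggplot2::facet_wrap(~state) +
             ggplot2::theme_minimal())
  }
  K <- object$K
  mats <- lapply(seq_len(nrow(object$centroids)), function(s) {
    m <- matrix(0, K, K)
    m[upper.tri(m)] <- object$centroids[s, ]
    m <- m + t(m)
    diag(m) <- 1
    m
  })
  long <- dplyr::bind_rows(lapply(seq_along(mats), function(s) {
    tibble(state = s, row = rep(seq_len(K), K), col = rep(seq_len(K), each = K),
           rho = as.vector(mats[[s]]))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_wrap(~state) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Save a state model as JSON
#'
#' @param model A `state_model`.
#' @param path JSON path.
#' @export
write_state_model <- function(model, path) {
  jsonlite::write_json(
    list(k_states = model$k_states, centroids = model$centroids,
         inertia = model$inertia, K = model$K, use_upper = model$use_upper,
         zscore = model$zscore, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Elementwise group test on FNC matrices with FDR control
#'
#' Welch two-sample t-test on every upper-triangle cell across subjects,
#' Benjamini-Hochberg correction over the K(K-1)/2 p-values at level `q`,
#' and the significance mask mirrored to the full matrix.
#'
#' @param mats_c,mats_s Lists (>= 2 each) of same-size `fnc_matrix` objects
#'   (controls first).
#' @param q FDR level.
#' @return An `fnc_test`: `t` and `p` matrices, BH-adjusted `p_adj`, logical
#'   `sig` matrix, and `q`.
#' @export
fnc_group_test <- function(mats_c, mats_s, q = 0.05) {
  stopifnot(length(mats_c) >= 2, length(mats_s) >= 2, q > 0, q < 1)
  K <- nrow(mats_c[[1]])
  ut <- upper.tri(matrix(0, K, K))
  Mc <- vapply(mats_c, function(m) unclass(m)[ut], numeric(sum(ut)))
  Ms <- vapply(mats_s, function(m) unclass(m)[ut], numeric(sum(ut)))
  if (!is.matrix(Mc)) Mc <- matrix(Mc, nrow = 1)
  if (!is.matrix(Ms)) Ms <- matrix(Ms, nrow = 1)
  w <- welch_rows(Mc, Ms)
  p_adj <- p.adjust(w$p, method = "BH")
  fill <- function(v, diag_val = 0) {
    m <- matrix(diag_val, K, K, dimnames = dimnames(mats_c[[1]]))
    m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  sig <- fill(as.numeric(!is.na(p_adj) & p_adj <= q), diag_val = 0) > 0
  structure(list(t = fill(w$t), p = fill(w$p, diag_val = NA),
                 p_adj = fill(p_adj, diag_val = NA), sig = sig, q = q,
                 n_c = w$n_c, n_s = w$n_s),
            class = "fnc_test")
}

#' @export
#' @method tidy fnc_test
tidy.fnc_test <- function(x, ...) {
  K <- nrow(x$t)
  ut <- upper.tri(x$t)
  labels <- rownames(x$t) %||% as.character(seq_len(K))
  tibble(row = labels[row(x$t)[ut]], col = labels[col(x$t)[ut]],
         statistic = x$t[ut], p.value = x$p[ut], p.adjusted = x$p_adj[ut],
         significant = x$sig[ut])
}

#' @export
#' @method glance fnc_test
glance.fnc_test <- function(x, ...) {
  ut <- upper.tri(x$t)
  tibble(n_pairs = sum(ut), n_significant = sum(x$sig[ut]),
         q = x$q, n_c = x$n_c, n_s = x$n_s)
}
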