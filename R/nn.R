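# Forward/backward execution of the model plan. Tensors are dense arrays of
# dim (nx, ny, nz, channels, batch); convolution and pooling kernels live in
# src/conv3d.cpp, normalization and the cheap elementwise ops here.

NORM_EPS <- 1e-5

# running-statistics momentum; overridden during post-training recalibration
.nn_opts <- new.env(parent = emptyenv())
.nn_opts$momentum <- 0.1
norm_momentum <- function() .nn_opts$momentum

# Normalization over (voxels x batch) per channel ("batch") or over voxels
# per (channel, sample) ("instance"). Returns y plus a cache for backward.
norm_fwd <- function(x, gamma, beta, type, training, run_mean = NULL,
                     run_var = NULL) {
  d <- dim(x)
  V <- prod(d[1:3]); C <- d[4]; B <- d[5]
  M <- matrix(x, V, C * B)
  if (type == "batch") {
    if (training || is.null(run_mean)) {
      mu <- rowMeans(matrix(colMeans(M), C, B))
      m2 <- rowMeans(matrix(colMeans(M^2), C, B))
      vr <- pmax(m2 - mu^2, 0)
    } else {
      mu <- run_mean; vr <- run_var
    }
    mu_col <- rep(mu, times = B); inv_col <- rep(1 / sqrt(vr + NORM_EPS), times = B)
  } else {
    mu_col <- colMeans(M)
    vr_col <- pmax(colMeans(M^2) - mu_col^2, 0)
    inv_col <- 1 / sqrt(vr_col + NORM_EPS)
    mu <- mu_col; vr <- vr_col
  }
  xhat <- (M - rep(mu_col, each = V)) * rep(inv_col, each = V)
  y <- xhat * rep(rep(gamma, times = B), each = V) +
    rep(rep(beta, times = B), each = V)
  dim(y) <- d
  new_run <- NULL
  if (type == "batch" && training) {
    mom <- norm_momentum()
    new_run <- list(
      mean = (1 - mom) * (run_mean %||% numeric(C)) + mom * mu,
      var = (1 - mom) * (run_var %||% rep(1, C)) + mom * vr
    )
  }
  list(y = y, cache = list(xhat = xhat, inv_col = inv_col, dims = d,
                           gamma = gamma, type = type),
       new_run = new_run)
}

norm_bwd <- function(cache, dy) {
  d <- cache$dims
  V <- prod(d[1:3]); C <- d[4]; B <- d[5]
  G <- matrix(dy, V, C * B)
  xhat <- cache$xhat
  per_channel <- function(colsums) rowSums(matrix(colsums, C, B))
  dgamma <- per_channel(colSums(G * xhat))
  dbeta <- per_channel(colSums(G))
  dxhat <- G * rep(rep(cache$gamma, times = B), each = V)
  if (cache$type == "batch") {
    n <- V * B
    s1 <- rep(per_channel(colSums(dxhat)), times = B)
    s2 <- rep(per_channel(colSums(dxhat * xhat)), times = B)
  } else {
    n <- V
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
  }
  dx <- (dxhat - rep(s1, each = V) / n - xhat * rep(s2, each = V) / n) *
    rep(cache$inv_col, each = V)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Run the plan. `training` enables dropout, batch statistics and running-stat
# updates; dropout masks draw from the current RNG state.
nn_forward <- function(model, x, training = FALSE) {
  plan <- model$plan
  P <- model$params
  S <- model$state
  spec <- model$spec
  cache <- vector("list", length(plan))
  skips <- list()
  h <- x
  for (i in seq_along(plan)) {
    op <- plan[[i]]
    switch(op$type,
      conv = {
        cache[[i]] <- h
        h <- .conv3d_fwd(h, P[[paste0(op$name, ".W")]],
                         P[[paste0(op$name, ".b")]], op$pad)
      },
      norm = {
        r <- norm_fwd(h, P[[paste0(op$name, ".gamma")]],
                      P[[paste0(op$name, ".beta")]], spec$norm, training,
                      S[[paste0(op$name, ".mean")]],
                      S[[paste0(op$name, ".var")]])
        cache[[i]] <- r$cache
        if (!is.null(r$new_run)) {
          S[[paste0(op$name, ".mean")]] <- r$new_run$mean
          S[[paste0(op$name, ".var")]] <- r$new_run$var
        }
        h <- r$y
      },
      pool = {
        r <- .maxpool3_fwd(h)
        cache[[i]] <- list(idx = r$idx, in_dims = dim(h)[1:3])
        h <- r$y
      },
      dropout = {
        if (training && spec$dropout_rate > 0) {
          mask <- array(
            (runif(length(h)) >= spec$dropout_rate) / (1 - spec$dropout_rate),
            dim = dim(h))
          cache[[i]] <- mask
          h <- h * mask
        }
      },
      sigmoid = {
        h <- sigmoid(h)
        cache[[i]] <- h
      },
      save_skip = {
        skips[[op$tag]] <- h
      },
      add_skip = {
        h <- h + skips[[op$tag]]
      }
    )
  }
  list(out = h, cache = cache, state = S)
}

nn_backward <- function(model, cache, dout) {
  plan <- model$plan
  P <- model$params
  grads <- list()
  gskips <- list()
  g <- dout
  for (i in rev(seq_along(plan))) {
    op <- plan[[i]]
    switch(op$type,
      conv = {
        r <- .conv3d_bwd(cache[[i]], P[[paste0(op$name, ".W")]], g, op$pad)
        grads[[paste0(op$name, ".W")]] <- r$dw
        grads[[paste0(op$name, ".b")]] <- r$db
        g <- r$dx
      },
      norm = {
        r <- norm_bwd(cache[[i]], g)
        grads[[paste0(op$name, ".gamma")]] <- r$dgamma
        grads[[paste0(op$name, ".beta")]] <- r$dbeta
        g <- r$dx
      },
      pool = {
        g <- .maxpool3_bwd(g, cache[[i]]$idx, cache[[i]]$in_dims)
      },
      dropout = {
        if (!is.null(cache[[i]])) g <- g * cache[[i]]
      },
      sigmoid = {
        y <- cache[[i]]
        g <- g * y * (1 - y)
      },
      save_skip = {
        if (!is.null(gskips[[op$tag]])) g <- g + gskips[[op$tag]]
      },
      add_skip = {
        gskips[[op$tag]] <- if (is.null(gskips[[op$tag]])) g else gskips[[op$tag]] + g
      }
    )
  }
  grads
}

#' Apply the model to a batch of 3D volumes
#'
#' Runs the regressor in evaluation mode (dropout off, batch normalization
#' using running statistics): the same input always yields the same output,
#' and outputs lie in `[0, 1]` because of the terminal sigmoid.
#'
#' @param model A [build_model()] result.
#' @param x A 3D array matching the model's `input_dims`, or a 4D array
#'   `(x, y, z, batch)` of such volumes.
#' @return Score volume(s) with the same spatial dimensionality as `x`.
#' @export
forward_volume <- function(model, x) {
  stopifnot(inherits(model, "parc_model"))
  assert_finite(x, "input volume")
  d <- dim(x)
  single <- length(d) == 3
  if (single) d <- c(d, 1L)
  if (length(d) != 4 || !identical(as.integer(d[1:3]), model$input_dims)) {
    abort(sprintf("input dims %s do not match model input dims %s",
                  fmt_dims(dim(x)), fmt_dims(model$input_dims)))
  }
  dim(x) <- c(d[1:3], 1L, d[4])
  out <- nn_forward(model, x, training = FALSE)$out
  dim(out) <- d
  if (single) dim(out) <- d[1:3]
  out
}

#' Predict per-network 4D score maps for one subject
#'
#' Applies one trained model per network to every timepoint of a 4D fMRI
#' volume and stacks the resulting score volumes into one 4D score map per
#' network (the subject's 5D representation).
#'
#' @param models List of `parc_model` objects, one per network.
#' @param volume 4D array `(x, y, z, t)`.
#' @param batch_size Timepoints processed per forward pass.
#' @return Named list of 4D score maps, one per network.
#' @export
predict_subject <- function(models, volume, batch_size = 5L) {
  stopifnot(is.list(models), length(models) >= 1, length(dim(volume)) == 4)
  d <- dim(volume)
  lapply(seq_along(models), function(k) {
    m <- models[[k]]
    if (!identical(as.integer(d[1:3]), m$input_dims)) {
      abort(sprintf("network %s: volume dims %s do not match model input dims %s",
                    m$network_id %||% k, fmt_dims(d[1:3]), fmt_dims(m$input_dims)))
    }
    out <- array(0, dim = d)
    for (start in seq(1, d[4], by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, d[4])
      out[, , , idx] <- forward_volume(m, volume[, , , idx, drop = FALSE])
    }
    out
  }) |> setNames(names(models) %||% paste0("net", seq_along(models)))
}


# Recompute batch-norm running statistics for the current parameters by one
# cumulative-average pass over a sample set (eval-mode outputs then match
# the statistics of the weights actually returned, instead of a moving
# average over the whole last epoch).
recalibrate_bn <- function(model, samples, batch_size = 5L) {
  if (model$spec$norm != "batch") return(model)
  i <- 0L
  for (start in seq(1, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(samples))
    x <- stack_samples(samples[idx], "input")
    i <- i + 1L
    .nn_opts$momentum <- 1 / i
    fw <- tryCatch(nn_forward(model, x, training = TRUE),
                   finally = {.nn_opts$momentum <- 0.1})
    model$state <- fw$state
  }
  model
}
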