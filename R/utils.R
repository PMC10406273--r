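# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a base seed and a few integer
# tags (subject index, group, stream id). Arithmetic in double to avoid
# integer overflow, reduced mod 2^31 - 1.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed)
  for (t in tags) s <- (s * 1009 + as.double(t) * 97 + 17) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Stationary AR(1) series with (asymptotically) unit marginal variance,
# one per column; a short burn-in removes the zero-start transient.
ar1_series <- function(n, k, phi = 0.9, burn = 25L) {
  e <- matrix(rnorm((n + burn) * k, sd = sqrt(1 - phi^2)), n + burn, k)
  x <- apply(e, 2, function(col) stats::filter(col, phi, method = "recursive"))
  matrix(x[(burn + 1):(burn + n), ], n, k)
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) abort(sprintf("%s contains non-finite values", what))
  invisible(x)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

fmt_dims <- function(d) paste(d, collapse = " x ")
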