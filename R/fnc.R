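#' Sliding-window specification for dynamic FNC
#'
#' Rectangular (untapered) windows of `window_length` timepoints;
#' consecutive windows share `overlap` timepoints, so the stride is
#' `window_length - overlap`. The defaults (length 30, overlap 10, stride
#' 20) give 7 windows for a 150-timepoint scan.
#'
#' @param window_length Timepoints per window.
#' @param overlap Timepoints shared by consecutive windows
#'   (`1 <= overlap < window_length`).
#' @return A `window_spec`.
#' @export
window_spec <- function(window_length = 30L, overlap = 10L) {
  stopifnot(is_count(window_length), is_count(overlap),
            overlap >= 1, overlap < window_length)
  structure(list(window_length = as.integer(window_length),
                 overlap = as.integer(overlap),
                 stride = as.integer(window_length - overlap)),
            class = "window_spec")
}

flatten_map <- function(w, mask_idx) {
  d <- dim(w)
  m <- matrix(w, prod(d[1:3]), d[4])
  as.vector(m[mask_idx, , drop = FALSE])
}

#' Static FNC between two 4D score maps
#'
#' Pearson correlation of the two maps flattened over (masked voxels x all
#' timepoints). If either flattened vector has zero variance the
#' correlation is undefined and reported as `NA`.
#'
#' @param wp,wq 4D maps on the same grid with the same number of timepoints.
#' @param mask Optional logical 3D array (non-empty).
#' @return A correlation in `[-1, 1]`, or `NA`.
#' @export
sfnc_pair <- function(wp, wq, mask = NULL) {
  stopifnot(identical(dim(wp), dim(wq)))
  d <- dim(wp)
  mask_idx <- if (is.null(mask)) seq_len(prod(d[1:3])) else which(mask)
  if (length(mask_idx) == 0) abort("empty mask")
  a <- flatten_map(wp, mask_idx)
  b <- flatten_map(wq, mask_idx)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Static FNC matrix of one subject
#'
#' Pearson correlations between all pairs of a subject's K 4D network maps,
#' each flattened over (masked voxels x timepoints): a symmetric K x K
#' matrix with unit diagonal, with networks ordered grouped by their
#' domains and labelled `<domain><index>` (e.g. `SM3`, `CB2`).
#'
#' @param maps List of K 4D score maps (K >= 2).
#' @param mask Optional logical 3D array.
#' @param domains Optional character vector of domain labels per network;
#'   enables domain grouping and labelling.
#' @param subject_id,window_id Carried as attributes.
#' @return An `fnc_matrix`.
#' @export
sfnc_matrix <- function(maps, mask = NULL, domains = NULL,
                        subject_id = NULL, window_id = NULL) {
  K <- length(maps)
  stopifnot(K >= 2)
  d <- dim(maps[[1]])
  mask_idx <- if (is.null(mask)) seq_len(prod(d[1:3])) else which(mask)
  if (length(mask_idx) == 0) abort("empty mask")

  ord <- seq_len(K)
  labels <- names(maps) %||% paste0("net", seq_len(K))
  if (!is.null(domains)) {
    stopifnot(length(domains) == K)
    ord <- order(match(domains, DOMAIN_NAMES), seq_len(K))
    labels <- paste0(domains[ord],
                     stats::ave(seq_along(ord), domains[ord], FUN = seq_along))
  }
  F <- vapply(maps[ord], flatten_map, numeric(length(mask_idx) * d[4]),
              mask_idx = mask_idx)
  zero_var <- apply(F, 2, sd) == 0
  R <- suppressWarnings(cor(F))
  R[zero_var, ] <- NA_real_
  R[, zero_var] <- NA_real_
  diag(R) <- 1
  dimnames(R) <- list(labels, labels)
  structure(R, class = c("fnc_matrix", "matrix", "array"),
            domains = if (!is.null(domains)) domains[ord],
            order = ord, subject_id = subject_id, window_id = window_id)
}

#' Dynamic FNC: one matrix per sliding window
#'
#' Applies [sfnc_matrix()] to consecutive windows of `spec$window_length`
#' timepoints starting at timepoint 1 with stride
#' `window_length - overlap`; a trailing remainder shorter than a full
#' window is dropped. The number of windows is
#' `floor((T - L) / (L - overlap)) + 1`.
#'
#' @param maps List of K 4D score maps.
#' @param spec A [window_spec()].
#' @param mask,domains,subject_id As in [sfnc_matrix()].
#' @return List of `fnc_matrix`, one per window.
#' @export
dfnc_windows <- function(maps, spec = window_spec(), mask = NULL,
                         domains = NULL, subject_id = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  T <- dim(maps[[1]])[4]
  if (T < spec$window_length) {
    abort(sprintf("scan has %d timepoints but the window needs %d",
                  T, spec$window_length))
  }
  starts <- seq(1L, T - spec$window_length + 1L, by = spec$stride)
  lapply(seq_along(starts), function(i) {
    span <- starts[i]:(starts[i] + spec$window_length - 1L)
    sliced <- lapply(maps, function(w) w[, , , span, drop = FALSE])
    sfnc_matrix(sliced, mask = mask, domains = domains,
                subject_id = subject_id, window_id = i)
  })
}

#' @export
#' @method tidy fnc_matrix
tidy.fnc_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(row = rep(rownames(m), times = ncol(m)),
         col = rep(colnames(m), each = nrow(m)),
         rho = as.vector(m))
}

#' @export
#' @method autoplot fnc_matrix
autoplot.fnc_matrix <- function(object, ...) {
  long <- tidy(object)
  long$row <- factor(long$row, levels = rev(rownames(object)))
  long$col <- factor(long$col, levels = colnames(object))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(rho)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write / read an FNC matrix as CSV with labelled headers
#'
#' @param x An `fnc_matrix` (or plain matrix).
#' @param path CSV path.
#' @export
write_fnc_csv <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}
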