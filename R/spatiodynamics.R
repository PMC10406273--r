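#' 3D summary maps
#'
#' A `map3d` is a 3D array on the analysis grid tagged with the kind of
#' summary it holds (`time_mean`, `temporal_deviation`, `group_mean`,
#' `group_deviation`, `difference` or `tstat`) and, optionally, a logical
#' brain mask.
#'
#' @param x 3D numeric array.
#' @param kind Summary kind tag.
#' @param mask Optional logical array of the same dimensions.
#' @return A `map3d` object.
#' @export
map3d <- function(x, kind = c("time_mean", "temporal_deviation", "group_mean",
                              "group_deviation", "difference", "tstat"),
                  mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(dim(x)) == 3)
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(x)), is.logical(mask))
  structure(x, kind = kind, mask = mask, class = c("map3d", "array"))
}

map_kind <- function(x) attr(x, "kind") %||% NA_character_

#' Voxel-wise time average of a 4D score map
#'
#' For each voxel, the mean over timepoints.
#'
#' @param w 4D array `(x, y, z, t)` with at least one timepoint.
#' @return A `map3d` of kind `time_mean`.
#' @export
time_mean <- function(w) {
  stopifnot(length(dim(w)) == 4)
  if (dim(w)[4] < 1) abort("empty time axis")
  map3d(rowMeans(w, dims = 3), "time_mean")
}

#' Voxel-wise temporal deviation of a 4D score map
#'
#' For each voxel, the sum of absolute differences between consecutive
#' timepoints — the spatial-dynamics summary. Zero exactly at voxels whose
#' series is constant in time; requires at least two timepoints.
#'
#' @param w 4D array `(x, y, z, t)`, `t >= 2`.
#' @return A `map3d` of kind `temporal_deviation` (elementwise >= 0).
#' @export
temporal_deviation <- function(w) {
  stopifnot(length(dim(w)) == 4)
  T <- dim(w)[4]
  if (T < 2) abort("temporal deviation is undefined for fewer than 2 timepoints")
  d <- abs(w[, , , 2:T, drop = FALSE] - w[, , , 1:(T - 1), drop = FALSE])
  map3d(rowSums(d, dims = 3), "temporal_deviation")
}

#' Voxel-wise average over subjects
#'
#' Averages same-kind, same-grid subject maps voxel by voxel, promoting
#' `time_mean` to `group_mean` and `temporal_deviation` to
#' `group_deviation`.
#'
#' @param maps Non-empty list of `map3d` objects of identical kind and grid.
#' @return A `map3d`.
#' @export
subject_mean <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1)
  kinds <- unique(vapply(maps, map_kind, ""))
  dims <- unique(lapply(maps, dim))
  if (length(kinds) != 1) abort("cannot average maps of mixed kinds")
  if (length(dims) != 1) abort("cannot average maps on different grids")
  out <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  kind <- switch(kinds, time_mean = "group_mean",
                 temporal_deviation = "group_deviation", kinds)
  map3d(out, kind)
}

# Vectorized Welch statistics over rows of two value matrices (rows =
# features, columns = group members). Returns t, Welch-Satterthwaite df and
# two-sided p; zero-pooled-variance rows get t = 0 and valid = FALSE.
welch_rows <- function(Mc, Ms) {
  nc <- ncol(Mc); ns <- ncol(Ms)
  stopifnot(nc >= 2, ns >= 2)
  mc <- rowMeans(Mc); ms <- rowMeans(Ms)
  vc <- rowSums((Mc - mc)^2) / (nc - 1)
  vs <- rowSums((Ms - ms)^2) / (ns - 1)
  se2 <- vc / nc + vs / ns
  valid <- se2 > 0
  t <- ifelse(valid, (mc - ms) / sqrt(se2), 0)
  df <- ifelse(valid,
               se2^2 / ((vc / nc)^2 / (nc - 1) + (vs / ns)^2 / (ns - 1)),
               NA_real_)
  p <- ifelse(valid, 2 * pt(-abs(t), df), NA_real_)
  list(t = t, df = df, p = p, mean_c = mc, mean_s = ms, var_c = vc, var_s = vs,
       valid = valid, n_c = nc, n_s = ns)
}

#' Voxel-wise two-sample (Welch) t-test between groups
#'
#' For each voxel, the Welch statistic
#' `t = (mean_c - mean_s) / sqrt(var_c/n_c + var_s/n_s)` with sample
#' variances (denominator n-1) computed across subjects within each group;
#' two-sided p-values use the t distribution with Welch-Satterthwaite
#' degrees of freedom. Voxels where both group variances are zero get
#' `t = 0` and are excluded from the validity mask rather than reported as
#' infinite.
#'
#' @param group_c,group_s Lists (>= 2 each) of same-grid 3D maps (controls
#'   first: positive t means control > patient).
#' @param mask Optional logical array restricting the analysis.
#' @return A `tstat_result`: t-map (`map3d`, kind `tstat`), per-voxel group
#'   means/variances, group sizes, p-map and validity mask.
#' @export
voxelwise_ttest <- function(group_c, group_s, mask = NULL) {
  stopifnot(length(group_c) >= 2, length(group_s) >= 2)
  d <- dim(group_c[[1]])
  stopifnot(all(vapply(c(group_c, group_s),
                       function(m) identical(dim(m), d), logical(1))))
  Mc <- vapply(group_c, as.vector, numeric(prod(d)))
  Ms <- vapply(group_s, as.vector, numeric(prod(d)))
  if (!is.matrix(Mc)) Mc <- matrix(Mc, nrow = 1)
  if (!is.matrix(Ms)) Ms <- matrix(Ms, nrow = 1)
  w <- welch_rows(Mc, Ms)
  to_arr <- function(v) array(v, dim = d)
  valid <- to_arr(w$valid)
  if (!is.null(mask)) valid <- valid & mask
  structure(
    list(t = map3d(to_arr(w$t), "tstat", mask = valid),
         mean_c = to_arr(w$mean_c), mean_s = to_arr(w$mean_s),
         var_c = to_arr(w$var_c), var_s = to_arr(w$var_s),
         n_c = w$n_c, n_s = w$n_s,
         p = to_arr(w$p), df = to_arr(w$df), valid = valid),
    class = "tstat_result"
  )
}

#' @export
#' @method tidy tstat_result
tidy.tstat_result <- function(x, ...) {
  d <- dim(x$t)
  coords <- arrayInd(seq_len(prod(d)), d)
  est <- as.vector(x$mean_c - x$mean_s)
  stat <- as.vector(unclass(x$t))
  pv <- as.vector(x$p)
  ok <- as.vector(x$valid)
  tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3],
         estimate = est, statistic = stat, p.value = pv, valid = ok)
}

#' @export
#' @method glance tstat_result
glance.tstat_result <- function(x, ...) {
  tibble(n_voxels = length(x$t), n_valid = sum(x$valid),
         n_c = x$n_c, n_s = x$n_s,
         rejections_05 = sum(x$p[x$valid] < 0.05, na.rm = TRUE))
}

#' Voxel-wise group difference map
#'
#' @param mean_c,mean_s Same-grid 3D group-mean maps (control minus patient).
#' @return A `map3d` of kind `difference`.
#' @export
difference_map <- function(mean_c, mean_s) {
  if (!identical(dim(mean_c), dim(mean_s))) abort("grid mismatch between group maps")
  map3d(unclass(mean_c) - unclass(mean_s), "difference")
}

#' Locate the positive and negative peak voxels of a difference map
#'
#' The positive peak is the argmax of the map over the positive-valued
#' masked voxels and the negative peak the argmin over the negative-valued
#' ones; an absent segment (e.g. an all-positive map) yields a missing peak.
#' Ties resolve to the lexicographically first voxel in array order.
#'
#' @param diff A 3D difference map.
#' @param mask Optional logical array; must select at least one voxel.
#' @return A `peak_selection` with `positive` and `negative` voxel
#'   coordinates (or `NULL` when missing).
#' @export
select_peaks <- function(diff, mask = NULL) {
  d <- dim(diff)
  mask <- mask %||% array(TRUE, dim = d)
  if (!any(mask)) abort("empty mask")
  v <- unclass(diff)
  pick <- function(sign) {
    cand <- mask & (if (sign > 0) v > 0 else v < 0)
    if (!any(cand)) return(NULL)
    vv <- ifelse(cand, v, NA_real_)
    idx <- if (sign > 0) which.max(vv) else which.min(vv)
    as.integer(arrayInd(idx, d))
  }
  structure(list(positive = pick(1), negative = pick(-1), values = NULL),
            class = "peak_selection")
}

#' Gather per-subject values at the selected peak voxels
#'
#' @param selection A [select_peaks()] result.
#' @param subject_maps Tibble with columns `subject_id`, `group`, `map`
#'   (list column of 3D maps, typically each subject's time-mean map).
#' @return The selection with `values`: a tibble
#'   (`subject_id`, `group`, `peak_sign`, `value`).
#' @export
collect_peak_values <- function(selection, subject_maps) {
  stopifnot(inherits(selection, "peak_selection"),
            all(c("subject_id", "group", "map") %in% names(subject_maps)))
  rows <- list()
  for (sign in c("positive", "negative")) {
    at <- selection[[sign]]
    if (is.null(at)) next
    vals <- vapply(subject_maps$map, function(m) m[at[1], at[2], at[3]],
                   numeric(1))
    rows[[sign]] <- tibble(subject_id = subject_maps$subject_id,
                           group = subject_maps$group,
                           peak_sign = sign, value = vals)
  }
  selection$values <- dplyr::bind_rows(rows)
  selection
}

#' Threshold a map into a region-of-interest mask
#'
#' Either an absolute-value cutoff (`|v| >= cutoff`) or an upper-quantile
#' rule (`v >` the q-th quantile of the map). Stricter rules produce subset
#' masks.
#'
#' @param map 3D map.
#' @param cutoff Absolute-value cutoff (mutually exclusive with `quantile`).
#' @param quantile Upper quantile in (0, 1).
#' @return Logical array.
#' @export
threshold_mask <- function(map, cutoff = NULL, quantile = NULL) {
  if (is.null(cutoff) == is.null(quantile)) {
    abort("supply exactly one of `cutoff` or `quantile`")
  }
  v <- unclass(map)
  if (!is.null(cutoff)) {
    stopifnot(cutoff >= 0)
    return(abs(v) >= cutoff)
  }
  if (quantile <= 0 || quantile >= 1) abort("quantile must be inside (0, 1)")
  v > stats::quantile(v, quantile)
}
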