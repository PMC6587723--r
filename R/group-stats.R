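# Group-level statistics: one-sample and paired t maps, percent change,
# GM-masked summaries, test-retest variance.

#' Construct a statistic map
#'
#' @param values 3D array (may contain `NA` for undefined voxels).
#' @param statistic one of `"t_one_sample"`, `"t_paired"`,
#'   `"percent_change"`, `"variance"`.
#' @param n_subjects number of subjects that entered the statistic.
#' @param mask logical 3D array over which the statistic is defined.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, statistic, n_subjects, mask) {
  statistic <- match.arg(statistic, c("t_one_sample", "t_paired",
                                      "percent_change", "variance"))
  stopifnot(length(dim(values)) == 3L, identical(dim(values), dim(mask)))
  structure(list(values = values, statistic = statistic,
                 n_subjects = as.integer(n_subjects), mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<stat_map> %s, n = %d, %dx%dx%d (%d in-mask voxels)\n",
              x$statistic, x$n_subjects, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

# list of fluctuation_maps / stat_maps / arrays -> 3D value arrays
.map_values <- function(maps) {
  lapply(maps, function(m) {
    if (inherits(m, c("fluctuation_map", "stat_map"))) m$values else m
  })
}

.common_mask <- function(maps, mask) {
  if (!is.null(mask)) return(mask)
  for (m in maps) {
    if (inherits(m, c("fluctuation_map", "stat_map"))) return(m$mask)
  }
  array(TRUE, dim = dim(.map_values(maps)[[1]]))
}

#' Voxelwise one-sample t map
#'
#' `t = mean / (sd / sqrt(n))` across subjects at each voxel.  Voxels with
#' zero across-subject SD (or any missing subject value) are flagged
#' missing rather than infinite.
#'
#' @param maps list of per-subject maps (`fluctuation_map`s or 3D arrays)
#'   on identical grids.
#' @param mask optional logical 3D array; defaults to the first map's mask.
#' @return A [stat_map()] with statistic `"t_one_sample"`.
#' @export
one_sample_t <- function(maps, mask = NULL) {
  vals <- .map_values(maps)
  n <- length(vals)
  if (n < 2L) stop("one_sample_t needs at least 2 subjects")
  dims <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), dims), TRUE)))
    stop("subject maps are on misaligned grids")
  mask <- .common_mask(maps, mask)
  stacked <- matrix(unlist(vals, use.names = FALSE), ncol = n)
  mu <- rowMeans(stacked)
  sdv <- apply(stacked, 1L, sd)
  t_val <- ifelse(is.finite(sdv) & sdv > 0, mu / (sdv / sqrt(n)), NA_real_)
  values <- array(t_val, dim = dims)
  values[!mask] <- NA_real_
  stat_map(values, "t_one_sample", n, mask)
}

#' Voxelwise paired t map
#'
#' One-sample t of the per-subject differences `maps_a - maps_b`.
#'
#' @param maps_a,maps_b lists of per-subject maps for the two conditions, in
#'   the same subject order and of equal length.
#' @param mask optional logical 3D array.
#' @return A [stat_map()] with statistic `"t_paired"`.
#' @export
paired_t <- function(maps_a, maps_b, mask = NULL) {
  if (length(maps_a) != length(maps_b))
    stop("paired_t needs the same subjects in both conditions")
  va <- .map_values(maps_a)
  vb <- .map_values(maps_b)
  diffs <- Map(function(a, b) {
    if (!identical(dim(a), dim(b))) stop("misaligned grids between conditions")
    a - b
  }, va, vb)
  out <- one_sample_t(diffs, mask = .common_mask(maps_a, mask))
  out$statistic <- "t_paired"
  out
}

#' Percent change between two statistic maps
#'
#' `100 * (with - without) / without` per voxel; voxels with a zero or
#' missing baseline are flagged missing.
#'
#' @param map_with,map_without `stat_map`s (or 3D arrays) on the same grid.
#' @param mask optional logical 3D array.
#' @return A [stat_map()] with statistic `"percent_change"`.
#' @export
percent_change <- function(map_with, map_without, mask = NULL) {
  vals <- .map_values(list(map_with, map_without))
  if (!identical(dim(vals[[1]]), dim(vals[[2]])))
    stop("maps are on misaligned grids")
  mask <- .common_mask(list(map_with, map_without), mask)
  base <- vals[[2]]
  pc <- ifelse(is.finite(base) & base != 0,
               100 * (vals[[1]] - base) / base, NA_real_)
  values <- array(pc, dim = dim(base))
  values[!mask] <- NA_real_
  n <- if (inherits(map_with, "stat_map")) map_with$n_subjects else 0L
  stat_map(values, "percent_change", n, mask)
}

#' Mean of a map over a mask
#'
#' Mean of in-mask, non-missing voxels.
#'
#' @param map a `stat_map`, `fluctuation_map` or 3D array.
#' @param mask logical 3D array.
#' @return A list with `mean` and `n_voxels` (the number of contributing
#'   voxels).
#' @export
masked_mean <- function(map, mask) {
  v <- .map_values(list(map))[[1]]
  stopifnot(identical(dim(v), dim(mask)))
  if (!any(mask)) stop("mask is empty")
  sel <- v[mask]
  sel <- sel[is.finite(sel)]
  if (length(sel) == 0L)
    stop("no finite in-mask voxels to average")
  list(mean = mean(sel), n_voxels = length(sel))
}

#' Test-retest variance map
#'
#' Per voxel, the unbiased (n-1) variance across each subject's sessions,
#' averaged over subjects.  Subjects with fewer than two sessions are
#' excluded with a warning.
#'
#' @param session_maps nested list: `session_maps[[subject]][[session]]`,
#'   each a `fluctuation_map` or 3D array.
#' @param mask optional logical 3D array.
#' @return A [stat_map()] with statistic `"variance"`.
#' @export
test_retest_variance <- function(session_maps, mask = NULL) {
  usable <- vapply(session_maps, length, 0L) >= 2L
  if (!all(usable)) {
    warning(sum(!usable), " subject(s) with a single session excluded ",
            "from test-retest variance")
    session_maps <- session_maps[usable]
  }
  if (length(session_maps) == 0L) stop("no subject has >= 2 sessions")
  mask <- .common_mask(session_maps[[1]], mask)
  per_subject <- lapply(session_maps, function(sessions) {
    vals <- .map_values(sessions)
    dims <- dim(vals[[1]])
    stacked <- matrix(unlist(vals, use.names = FALSE), ncol = length(vals))
    array(apply(stacked, 1L, var), dim = dims)
  })
  dims <- dim(per_subject[[1]])
  total <- Reduce(`+`, per_subject) / length(per_subject)
  values <- array(total, dim = dims)
  values[!mask] <- NA_real_
  stat_map(values, "variance", length(per_subject), mask)
}

#' Bonferroni-thresholded t map
#'
#' Plumbing for quick voxelwise inference: two-sided p values from the t
#' distribution, Bonferroni-corrected over in-mask voxels.  This is a plain
#' Bonferroni bound, not a random-field-theory family-wise error threshold.
#'
#' @param t_map a [stat_map()] with a t statistic.
#' @param alpha significance level (default 0.05).
#' @return Logical 3D array: voxels significant after correction.
#' @export
bonferroni_significant <- function(t_map, alpha = 0.05) {
  stopifnot(inherits(t_map, "stat_map"),
            t_map$statistic %in% c("t_one_sample", "t_paired"))
  df <- t_map$n_subjects - 1L
  v <- t_map$values
  p <- 2 * pt(abs(v), df = df, lower.tail = FALSE)
  m <- sum(t_map$mask & is.finite(v))
  sig <- array(FALSE, dim = dim(v))
  sel <- t_map$mask & is.finite(v)
  sig[sel] <- p.adjust(p[sel], method = "bonferroni", n = m) < alpha
  sig
}
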