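# Voxelwise fluctuation maps: computation, standardisation, smoothing,
# bias-field application/removal.

#' Construct a fluctuation map object
#'
#' Usually created by [compute_fluctuation_map()]; exported for programmatic
#' construction in tests and tools.
#'
#' @param values 3D array of nonnegative amplitudes (`NA` allowed for
#'   undefined voxels).
#' @param measure one of `"alff"`, `"falff"`, `"hfalff"`.
#' @param band `c(low, high)` in Hz.
#' @param mask logical 3D array of in-brain voxels.
#' @param standardised has the map been divided by its in-mask mean?
#' @param smoothing_fwhm_mm Gaussian smoothing applied, in mm (`NA` if none).
#' @return An object of class `fluctuation_map`.
#' @export
fluctuation_map <- function(values, measure, band, mask,
                            standardised = FALSE,
                            smoothing_fwhm_mm = NA_real_) {
  measure <- match.arg(tolower(measure), c("alff", "falff", "hfalff"))
  stopifnot(length(dim(values)) == 3L, identical(dim(values), dim(mask)))
  if (any(values < 0, na.rm = TRUE))
    stop("fluctuation map values must be nonnegative")
  structure(list(values = values, measure = measure, band = band,
                 mask = mask, standardised = isTRUE(standardised),
                 smoothing_fwhm_mm = smoothing_fwhm_mm),
            class = "fluctuation_map")
}

#' @export
print.fluctuation_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<fluctuation_map> %s, band %g-%g Hz, %dx%dx%d, %sstandardised, fwhm %s mm\n",
    x$measure, x$band[1], x$band[2], d[1], d[2], d[3],
    if (x$standardised) "" else "not ",
    if (is.na(x$smoothing_fwhm_mm)) "-" else format(x$smoothing_fwhm_mm)))
  invisible(x)
}

# N x V matrix of the in-mask voxel time courses of a 4D array
.mask_timecourses <- function(bold_4d, mask) {
  d <- dim(bold_4d)
  stopifnot(length(d) == 4L, identical(d[1:3], dim(mask)))
  flat <- matrix(bold_4d, nrow = prod(d[1:3]), ncol = d[4])
  t(flat[which(mask), , drop = FALSE])
}

#' Compute a voxelwise fluctuation map from 4D data
#'
#' Fourier-transforms every in-mask voxel time course and evaluates the
#' requested measure ([alff()], [falff()] or [hfalff()]) per voxel.
#' Out-of-mask voxels are 0; in-mask voxels with a zero denominator
#' (flat series) become `NA`.
#'
#' @param bold_4d 4D array (x, y, z, time), all in-mask values finite.
#' @param tr_seconds sampling interval (s).
#' @param measure `"alff"`, `"falff"` or `"hfalff"`.
#' @param band `c(low, high)` in Hz.
#' @param mask logical 3D array; defaults to all voxels.
#' @return A [fluctuation_map()] (not yet standardised or smoothed).
#' @export
compute_fluctuation_map <- function(bold_4d, tr_seconds,
                                    measure = c("alff", "falff", "hfalff"),
                                    band = c(0.01, 0.1), mask = NULL) {
  measure <- match.arg(measure)
  d <- dim(bold_4d)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  tc <- .mask_timecourses(bold_4d, mask)
  if (any(!is.finite(tc))) {
    bad <- which(apply(!is.finite(tc), 2L, any))[1]
    stop("non-finite value in time course at in-mask voxel #", bad)
  }
  n <- d[4]
  if (n < 4) stop("need at least 4 time points")
  proto <- compute_spectrum(tc[, 1L], tr_seconds)
  .check_band(proto, band)
  nyq <- 1 / (2 * tr_seconds)
  mags <- Mod(mvfft(tc))[seq_len(n %/% 2 + 1L), , drop = FALSE]
  num_bins <- .spec_bins(proto, band[1], band[2])
  if (length(num_bins) == 0L)
    stop(sprintf("band %g-%g Hz contains no DFT bin (spacing %g Hz)",
                 band[1], band[2], 1 / (n * tr_seconds)))
  num <- colSums(mags[num_bins, , drop = FALSE])
  vals <- switch(measure,
    alff = num,
    falff = {
      den <- colSums(mags[.spec_bins(proto, 0, nyq), , drop = FALSE])
      ifelse(den > 0, num / den, NA_real_)
    },
    hfalff = {
      den <- colSums(mags[.spec_bins(proto, band[1], nyq), , drop = FALSE])
      ifelse(den > 0, num / den, NA_real_)
    })
  values <- array(0, dim = d[1:3])
  values[which(mask)] <- vals
  fluctuation_map(values, measure, band, mask)
}

#' Standardise a fluctuation map by its in-mask mean
#'
#' Divides the map by the mean over in-mask, non-missing voxels, so the
#' in-mask mean of the result is exactly 1; out-of-mask voxels are set to 0.
#' Idempotent.
#'
#' @param map a [fluctuation_map()].
#' @param brain_mask logical 3D array; defaults to the map's own mask.
#' @return The standardised `fluctuation_map`.
#' @export
standardise_map <- function(map, brain_mask = NULL) {
  stopifnot(inherits(map, "fluctuation_map"))
  if (is.null(brain_mask)) brain_mask <- map$mask
  stopifnot(identical(dim(brain_mask), dim(map$values)))
  if (!any(brain_mask)) stop("brain mask is empty")
  m <- mean(map$values[brain_mask], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("in-mask mean must be positive to standardise")
  values <- array(0, dim = dim(map$values))
  values[brain_mask] <- map$values[brain_mask] / m
  fluctuation_map(values, map$measure, map$band, brain_mask,
                  standardised = TRUE,
                  smoothing_fwhm_mm = map$smoothing_fwhm_mm)
}

# 1D Gaussian convolution along one array axis with reflecting boundaries.
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

.reflect_idx <- function(i, n) {
  # reflect about the edges (SPM-style 'mirror' boundary)
  i <- ((i - 1) %% (2 * n))
  ifelse(i < n, i + 1, 2 * n - i)
}

.smooth_axis <- function(vol, axis, sigma) {
  if (sigma <= 0) return(vol)
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  d <- dim(vol)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  dim(v) <- c(n, prod(d[perm[2:3]]))
  out <- matrix(0, nrow = n, ncol = ncol(v))
  for (j in seq_along(k)) {
    rows <- .reflect_idx(seq_len(n) + (j - 1L - r), n)
    out <- out + k[j] * v[rows, , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Gaussian smoothing of a fluctuation map
#'
#' Separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis in voxel units and
#' reflecting boundaries.  `fwhm = 0` is the identity.  Missing voxels are
#' treated as 0 during convolution.
#'
#' @param map a [fluctuation_map()].
#' @param fwhm_mm full width at half maximum in mm (>= 0).
#' @param voxel_size_mm numeric vector of 3 voxel edge lengths (mm).
#' @return The smoothed `fluctuation_map`.
#' @export
gaussian_smooth <- function(map, fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  stopifnot(inherits(map, "fluctuation_map"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(map)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  values <- map$values
  values[is.na(values)] <- 0
  for (ax in 1:3) values <- .smooth_axis(values, ax, sigma_vox[ax])
  values[values < 0] <- 0          # guard against tiny negative ringing
  fluctuation_map(values, map$measure, map$band, map$mask,
                  standardised = map$standardised,
                  smoothing_fwhm_mm = fwhm_mm)
}

#' Apply (remove) a multiplicative bias field
#'
#' Divides every time point of a 4D data set voxelwise by a positive gain
#' field.  ALFF of the corrected data scales by `1/gain`; fALFF and hfALFF
#' are unchanged.
#'
#' @param bold_4d 4D array (x, y, z, time).
#' @param bias_field positive 3D array matching the spatial dimensions.
#' @return The corrected 4D array.
#' @export
apply_bias_correction <- function(bold_4d, bias_field) {
  d <- dim(bold_4d)
  stopifnot(length(d) == 4L, identical(d[1:3], dim(bias_field)))
  if (any(!is.finite(bias_field)) || any(bias_field <= 0))
    stop("bias field must be positive everywhere")
  array(as.vector(bold_4d) / as.vector(bias_field), dim = d)
}
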