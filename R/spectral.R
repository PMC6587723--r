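# Voxelwise spectral amplitude measures: ALFF, fALFF, hfALFF.
#
# Conventions (fixed package-wide):
#   * magnitudes are |unnormalised forward DFT coefficient|, one-sided,
#     without doubling — any fixed convention cancels in the fractional
#     measures and only rescales ALFF before standardisation;
#   * the DC bin is excluded from every numerator and denominator: it
#     encodes the baseline, not fluctuation, and keeping it would break
#     the multiplicative-gain invariance of fALFF/hfALFF;
#   * band edges are closed: bins with low <= f <= high count as in-band;
#   * for even N the Nyquist bin is included once; for odd N the last
#     one-sided bin is floor(N/2).

#' One-sided magnitude spectrum of a time course
#'
#' @param timecourse numeric vector, length >= 4, all finite.
#' @param tr_seconds sampling interval (s).
#' @param voxel optional label used in error messages.
#' @return An object of class `lff_spectrum` with fields `magnitudes`
#'   (length `floor(N/2) + 1`), `frequencies` (Hz; `frequencies[1]` is 0),
#'   `n_timepoints` and `tr_seconds`.
#' @export
#' @examples
#' sp <- compute_spectrum(sin(2 * pi * 4 * (0:63) / 64), tr_seconds = 2)
#' sp$frequencies[which.max(sp$magnitudes)]
compute_spectrum <- function(timecourse, tr_seconds, voxel = NULL) {
  n <- length(timecourse)
  if (n < 4) stop("time course must have length >= 4")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (any(!is.finite(timecourse)))
    stop("non-finite value in time course",
         if (!is.null(voxel)) paste0(" at voxel ", voxel) else "")
  k <- 0:(n %/% 2)
  z <- fft(timecourse)
  structure(list(
    magnitudes = Mod(z[k + 1L]),
    frequencies = k / (n * tr_seconds),
    n_timepoints = n,
    tr_seconds = tr_seconds
  ), class = "lff_spectrum")
}

# indices into a spectrum's one-sided bins with low <= f <= high, DC excluded
.spec_bins <- function(spectrum, low, high) {
  f <- spectrum$frequencies
  tol <- 1e-12
  which(f > tol & f >= low - tol & f <= high + tol)
}

.check_band <- function(spectrum, band) {
  nyq <- 1 / (2 * spectrum$tr_seconds)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] > nyq + 1e-12)
    stop(sprintf("band must satisfy 0 < low < high <= Nyquist (%g Hz)", nyq))
  invisible(band)
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Sum of the one-sided DFT magnitudes over bins inside the band
#' (closed interval, DC excluded).
#'
#' @param spectrum an `lff_spectrum` from [compute_spectrum()].
#' @param band `c(low, high)` in Hz.
#' @return Nonnegative scalar; scales linearly with the input amplitude.
#' @export
alff <- function(spectrum, band = c(0.01, 0.1)) {
  .check_band(spectrum, band)
  bins <- .spec_bins(spectrum, band[1], band[2])
  if (length(bins) == 0L)
    stop(sprintf("band %g-%g Hz contains no DFT bin (spacing %g Hz)",
                 band[1], band[2], 1 /
                   (spectrum$n_timepoints * spectrum$tr_seconds)))
  sum(spectrum$magnitudes[bins])
}

#' Fractional ALFF (fALFF)
#'
#' ALFF divided by the sum of the magnitudes of all frequencies up to
#' Nyquist (DC excluded).  Invariant under any positive multiplicative gain
#' of the time course.
#'
#' @inheritParams alff
#' @param na_on_zero if `TRUE` return `NA_real_` on an all-zero denominator
#'   instead of signalling an error.
#' @return Value in `[0, 1]`, or `NA` for a flat series with
#'   `na_on_zero = TRUE`.
#' @export
falff <- function(spectrum, band = c(0.01, 0.1), na_on_zero = FALSE) {
  .check_band(spectrum, band)
  nyq <- 1 / (2 * spectrum$tr_seconds)
  den <- sum(spectrum$magnitudes[.spec_bins(spectrum, 0, nyq)])
  if (den <= 0) {
    if (na_on_zero) return(NA_real_)
    stop("all-zero spectrum: fALFF denominator is zero")
  }
  alff(spectrum, band) / den
}

#' High-frequency fractional ALFF (hfALFF)
#'
#' Like [falff()] but with all frequencies below the band's lower edge
#' excluded from the denominator, so that very slow drifts cannot enter the
#' normalisation: the denominator runs over `band[1] <= f <= Nyquist`.
#' Consequently `hfalff >= falff` always.
#'
#' @inheritParams falff
#' @return Value in `[0, 1]`, or `NA` as for [falff()].
#' @export
hfalff <- function(spectrum, band = c(0.01, 0.1), na_on_zero = FALSE) {
  .check_band(spectrum, band)
  nyq <- 1 / (2 * spectrum$tr_seconds)
  den <- sum(spectrum$magnitudes[.spec_bins(spectrum, band[1], nyq)])
  if (den <= 0) {
    if (na_on_zero) return(NA_real_)
    stop("all-zero high-frequency spectrum: hfALFF denominator is zero")
  }
  alff(spectrum, band) / den
}
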