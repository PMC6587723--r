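# Phase-randomised surrogate regressors and exploratory (lag-one CCA)
# trend estimation.

# Hermitian-symmetric random phase vector: phi[DC] = 0, phi[N-k] = -phi[k],
# and the Nyquist bin of an even-length series stays real, so the surrogate
# series are exactly real-valued.
.random_phase <- function(n) {
  phi <- numeric(n)
  half <- (n - 1L) %/% 2L
  if (half >= 1L) {
    ph <- runif(half, 0, 2 * pi)
    phi[2:(half + 1L)] <- ph
    phi[n:(n - half + 1L)] <- -ph
  }
  phi
}

#' Phase-randomised surrogate regressor sets
#'
#' For each repetition one random phase vector is drawn and added to the
#' Fourier phases of *every* regressor of that repetition (Hermitian
#' symmetry enforced; DC and the even-N Nyquist bin are left real).  The
#' surrogates are real, preserve each regressor's amplitude spectrum
#' exactly, and — because the phase is shared — preserve all pairwise
#' correlations between regressors.  Uses the current state of R's RNG.
#'
#' @param blocks a `regressor_block` or list of them (real-valued).
#' @param n_repetitions number of surrogate sets (default 25).
#' @return A list of length `n_repetitions`; each element is a list of
#'   `regressor_block`s mirroring `blocks`.
#' @export
phase_randomise <- function(blocks, n_repetitions = 25L) {
  single <- inherits(blocks, "regressor_block")
  if (single) blocks <- list(blocks)
  n <- nrow(blocks[[1]]$columns)
  lapply(seq_len(n_repetitions), function(rep_i) {
    rot <- exp(1i * .random_phase(n))
    lapply(blocks, function(b) {
      z <- mvfft(b$columns) * rot
      regressor_block(b$name, Re(mvfft(z, inverse = TRUE)) / n)
    })
  })
}

#' Exploratory trend regressors via lag-one CCA
#'
#' Estimates slow, highly autocorrelated trend time courses from non-GM
#' (WM and CSF) voxel data:
#' 1. demean each voxel time course;
#' 2. reduce to `d = ceiling(0.05 * N)` principal components;
#' 3. canonical correlation analysis between the reduced series at times
#'    `1..N-1` and its lag-one shifted version at times `2..N`;
#' 4. reconstruct each canonical variate over the full N time points by
#'    projecting the reduced data onto the canonical weight vectors;
#' 5. rank variates by their empirical lag-one autocorrelation (descending,
#'    ties broken by canonical-correlation order) and return the top
#'    `n_trends`.
#'
#' The returned block is of type `ExplTrend` and is deliberately exempt
#' from [orthogonalise()].
#'
#' @param timecourses N x V matrix of non-GM voxel time courses with
#'   `V > ceiling(0.05 * N)`.
#' @param n_trends number of trend regressors to return (default 4).
#' @return A `regressor_block` named `"ExplTrend"` with `n_trends` unit-SD
#'   columns, plus attributes `autocorrelations` and
#'   `canonical_correlations`.
#' @export
exploratory_trends <- function(timecourses, n_trends = 4L) {
  x <- as.matrix(timecourses)
  n <- nrow(x)
  v <- ncol(x)
  d <- ceiling(0.05 * n)
  if (d < n_trends)
    stop(sprintf(
      "PCA dimension ceiling(0.05*N) = %d is below n_trends = %d: use a longer series or fewer trends",
      d, n_trends))
  if (v <= d)
    stop(sprintf("need more than %d voxels for a %d-dimensional reduction",
                 d, d))
  centred <- sweep(x, 2L, colMeans(x))
  sv <- svd(centred, nu = d, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d)   # N x d reduced series

  cc <- cancor(scores[1:(n - 1L), , drop = FALSE],
               scores[2:n, , drop = FALSE])
  weights <- cc$xcoef[, seq_len(min(d, ncol(cc$xcoef))), drop = FALSE]
  variates <- sweep(scores, 2L, colMeans(scores)) %*% weights  # full length N

  ac1 <- apply(variates, 2L, function(z) {
    if (sd(z) == 0) return(0)
    cor(z[-n], z[-1L])
  })
  ord <- order(ac1, decreasing = TRUE)          # stable: ties keep CCA order
  if (length(ord) < n_trends)
    stop("CCA produced fewer variates than n_trends")
  top <- ord[seq_len(n_trends)]
  trends <- variates[, top, drop = FALSE]
  s <- apply(trends, 2L, sd)
  s[s == 0] <- 1
  trends <- sweep(trends, 2L, s, "/")
  out <- regressor_block("ExplTrend", trends)
  attr(out, "autocorrelations") <- ac1[top]
  attr(out, "canonical_correlations") <- cc$cor[top]
  out
}
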