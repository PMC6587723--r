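# Nuisance regressor blocks, orthogonalisation and least-squares removal
# (time domain and Fourier domain).

#' Construct a named regressor block
#'
#' @param name block name: one of `"Detr"`, `"WM"`, `"CSF"`, `"RP"`,
#'   `"ExplTrend"`.
#' @param columns N x k numeric matrix of regressor time courses; no column
#'   may be identically zero.
#' @return An object of class `regressor_block`.
#' @export
regressor_block <- function(name, columns) {
  name <- match.arg(name, c("Detr", "WM", "CSF", "RP", "ExplTrend"))
  columns <- as.matrix(columns)
  if (ncol(columns) < 1L) stop("block needs at least one column")
  if (any(!is.finite(columns))) stop("block columns must be finite")
  if (any(colSums(columns != 0) == 0L))
    stop("block contains an identically zero column")
  colnames(columns) <- sprintf("%s_%d", tolower(name), seq_len(ncol(columns)))
  structure(list(name = name, columns = columns), class = "regressor_block")
}

#' @export
print.regressor_block <- function(x, ...) {
  cat(sprintf("<regressor_block> %s: %d x %d\n", x$name,
              nrow(x$columns), ncol(x$columns)))
  invisible(x)
}

#' Polynomial trend block
#'
#' Constant, linear and quadratic regressors on a time axis normalised to
#' `[-1, 1]` — the detrending (`Detr`) nuisance block.
#'
#' @param n_timepoints series length (>= 4).
#' @return A `regressor_block` named `"Detr"` with 3 columns.
#' @export
polynomial_block <- function(n_timepoints) {
  if (n_timepoints < 4) stop("n_timepoints must be >= 4")
  t_norm <- seq(-1, 1, length.out = n_timepoints)
  regressor_block("Detr", cbind(rep(1, n_timepoints), t_norm, t_norm^2))
}

# One 6-connected morphological erosion pass of a logical 3D mask.
.erode_once <- function(mask) {
  d <- dim(mask)
  padded <- array(FALSE, dim = d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  out <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    out <- out & padded[(2:(d[1] + 1)) + s[1],
                        (2:(d[2] + 1)) + s[2],
                        (2:(d[3] + 1)) + s[3]]
  }
  out
}

#' Extract tissue time courses by thresholding and eroding a probability map
#'
#' The binary mask is `prob_map >= threshold`, then eroded
#' `erosion_voxels` times with 6-connectivity (volume boundaries count as
#' background).  Time courses of the surviving voxels are returned
#' column-wise.
#'
#' @param bold_4d 4D array (x, y, z, time).
#' @param prob_map 3D array of tissue probabilities in `[0, 1]`.
#' @param threshold probability threshold (default 0.9).
#' @param erosion_voxels number of erosion passes (default 1).
#' @return A list of class `tissue_extraction` with `mask` (logical 3D
#'   array), `timecourses` (N x V matrix), `threshold`, `erosion_voxels`.
#' @export
extract_tissue_timecourses <- function(bold_4d, prob_map, threshold = 0.9,
                                       erosion_voxels = 1L) {
  d <- dim(bold_4d)
  stopifnot(length(d) == 4L, identical(d[1:3], dim(prob_map)))
  if (any(prob_map < 0 | prob_map > 1))
    stop("prob_map values must lie in [0, 1]")
  mask <- prob_map >= threshold
  for (i in seq_len(erosion_voxels)) mask <- .erode_once(mask)
  if (!any(mask))
    stop(sprintf(
      "tissue mask empty after threshold %g and %d erosion pass(es)",
      threshold, erosion_voxels))
  structure(list(mask = mask,
                 timecourses = .mask_timecourses(bold_4d, mask),
                 threshold = threshold,
                 erosion_voxels = as.integer(erosion_voxels)),
            class = "tissue_extraction")
}

#' PCA tissue nuisance block
#'
#' The spatial-mean time course plus the first `n_components` temporal
#' principal components of the voxel-demeaned data (each voxel's temporal
#' mean removed; PCA on the covariance, not the correlation), ordered by
#' explained variance.  With the default 5 components this yields the
#' six-regressor WM or CSF block.
#'
#' @param timecourses N x V matrix (V >= `n_components + 1`).
#' @param n_components number of principal components (default 5).
#' @param name block name, `"WM"` or `"CSF"`.
#' @return A `regressor_block` with `n_components + 1` columns; the
#'   component columns are mutually orthogonal.
#' @export
pca_block <- function(timecourses, n_components = 5L, name = "WM") {
  x <- as.matrix(timecourses)
  v <- ncol(x)
  if (v < n_components + 1L)
    stop(sprintf("need at least %d voxels for %d components, got %d",
                 n_components + 1L, n_components, v))
  mean_tc <- rowMeans(x)
  centred <- sweep(x, 2L, colMeans(x))
  sv <- svd(centred, nu = n_components, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  regressor_block(name, cbind(mean_tc, pcs))
}

#' Realignment-parameter block
#'
#' The six rigid-body motion parameters are used as regressors unchanged:
#' no derivatives, no expansion.
#'
#' @param realignment_params N x 6 matrix (3 translations, 3 rotations).
#' @return A `regressor_block` named `"RP"`.
#' @export
rp_block <- function(realignment_params) {
  rp <- as.matrix(realignment_params)
  if (ncol(rp) != 6L)
    stop("realignment parameters must have exactly 6 columns, got ", ncol(rp))
  regressor_block("RP", rp)
}

#' Orthogonalise regressor blocks against the polynomial trends
#'
#' Removes from every column of the `WM`, `CSF` and `RP` blocks its
#' projection onto the constant/linear/quadratic regressors, via the QR
#' decomposition of the polynomial block.  `Detr` blocks pass through
#' unchanged, and `ExplTrend` blocks are deliberately never orthogonalised.
#' A column lying entirely in the polynomial span is dropped with a warning.
#'
#' @param blocks list of `regressor_block`s.
#' @param reference a polynomial `regressor_block`
#'   (default `polynomial_block(N)`).
#' @return The list of orthogonalised blocks (possibly with fewer columns;
#'   a block whose columns are all dropped is removed from the list).
#' @export
orthogonalise <- function(blocks, reference = NULL) {
  if (inherits(blocks, "regressor_block")) blocks <- list(blocks)
  n <- nrow(blocks[[1]]$columns)
  if (is.null(reference)) reference <- polynomial_block(n)
  stopifnot(inherits(reference, "regressor_block"))
  q <- qr.Q(qr(reference$columns))
  out <- list()
  for (b in blocks) {
    if (b$name %in% c("Detr", "ExplTrend")) {
      out[[length(out) + 1L]] <- b
      next
    }
    cols <- b$columns - q %*% (t(q) %*% b$columns)
    keep <- sqrt(colSums(cols^2)) >
      1e-10 * pmax(sqrt(colSums(b$columns^2)), 1)
    if (!all(keep))
      warning(sprintf(
        "%s: dropped %d column(s) lying in the polynomial span",
        b$name, sum(!keep)))
    if (any(keep))
      out[[length(out) + 1L]] <-
        regressor_block(b$name, cols[, keep, drop = FALSE])
  }
  out
}

#' Assemble a design matrix from regressor blocks
#'
#' Blocks are bound in the stable order Detr, WM, CSF, ExplTrend, RP
#' (mathematically irrelevant after orthogonalisation, fixed for
#' reproducibility).
#'
#' @param blocks list of `regressor_block`s.
#' @return An object of class `design_matrix` with fields `X` (N x p,
#'   full column rank, p < N) and `labels` (column provenance).
#' @export
design_matrix <- function(blocks) {
  if (inherits(blocks, "regressor_block")) blocks <- list(blocks)
  order_names <- c("Detr", "WM", "CSF", "ExplTrend", "RP")
  blocks <- blocks[order(match(vapply(blocks, `[[`, "", "name"),
                               order_names))]
  x <- do.call(cbind, lapply(blocks, `[[`, "columns"))
  if (ncol(x) >= nrow(x))
    stop("design has p >= N (", ncol(x), " >= ", nrow(x), ")")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dep <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  structure(list(X = x, labels = colnames(x), qr = qx),
            class = "design_matrix")
}

#' Remove fitted nuisance regressors from time courses
#'
#' Ordinary least squares: returns `y - X (X'X)^{-1} X'y`, making the
#' residuals orthogonal to every design column.  Idempotent and linear in
#' `y`.
#'
#' @param y numeric vector of length N or an N x V matrix of voxel time
#'   courses.
#' @param design a [design_matrix()] (or a list of `regressor_block`s,
#'   which is assembled first).
#' @return Residuals with the shape of `y`.
#' @export
regress_out <- function(y, design) {
  if (!inherits(design, "design_matrix")) design <- design_matrix(design)
  y_mat <- as.matrix(y)
  if (nrow(y_mat) != nrow(design$X))
    stop("y and design have different numbers of time points")
  res <- qr.resid(design$qr, y_mat)
  if (is.matrix(y)) res else drop(res)
}

#' Unitary DFT matrix
#'
#' The N x N matrix `U` with `U[k, n] = exp(-2i pi (k-1)(n-1) / N) / sqrt(N)`
#' satisfying `solve(U) == Conj(t(U))`.
#'
#' @param n size.
#' @return Complex N x N matrix.
#' @export
unitary_dft <- function(n) {
  kn <- outer(0:(n - 1), 0:(n - 1))
  exp(-2i * pi * kn / n) / sqrt(n)
}

#' Nuisance regression in the Fourier domain
#'
#' Least squares on the Fourier-transformed data and design:
#' `Yhat = (I - X (X^H X)^{-1} X^H) Y` with `^H` the conjugate transpose.
#' Because the DFT matrix is unitary, inverse-transforming the result
#' reproduces [regress_out()]'s time-domain residuals; the operation is a
#' linear transformation of the Fourier components in which frequencies mix.
#'
#' @param y_fourier complex vector or N x V matrix, `U %*% y`.
#' @param x_fourier complex N x p matrix, `U %*% X`.
#' @return Complex residual spectrum with the shape of `y_fourier`.
#' @export
regress_fourier <- function(y_fourier, x_fourier) {
  y_mat <- as.matrix(y_fourier)
  x <- as.matrix(x_fourier)
  if (nrow(y_mat) != nrow(x))
    stop("y and design have different numbers of frequency bins")
  xh <- Conj(t(x))
  gram <- xh %*% x
  sv <- svd(gram)$d
  if (min(sv) < 1e-12 * max(sv))
    stop("Fourier-domain design matrix is rank deficient")
  beta <- solve(gram, xh %*% y_mat)
  res <- y_mat - x %*% beta
  if (is.matrix(y_fourier)) res else drop(res)
}
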