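# Regressor blocks, orthogonalisation, least squares in time and Fourier
# domains, surrogates and exploratory trends.

test_that("polynomial block spans constant/linear/quadratic trends", {
  b <- polynomial_block(10)
  expect_equal(dim(b$columns), c(10L, 3L))
  expect_equal(qr(b$columns)$rank, 3L)

  t_norm <- seq(-1, 1, length.out = 64)
  y <- 4 + 3 * t_norm + 2 * t_norm^2
  res <- regress_out(y, list(polynomial_block(64)))
  expect_lt(max(abs(res)), 1e-9)

  # detrending an in-band sinusoid changes its ALFF by < 5%
  x <- exact_tone(256, k = 12)              # 12/512 ~ 0.023 Hz
  res <- regress_out(x, list(polynomial_block(256)))
  a0 <- alff(compute_spectrum(x, 2))
  a1 <- alff(compute_spectrum(res, 2))
  expect_lt(abs(a1 - a0) / a0, 0.05)
})

test_that("tissue extraction thresholds and erodes probability maps", {
  dims <- c(7, 7, 7)
  bold <- array(rnorm(prod(dims) * 20), dim = c(dims, 20))

  all_in <- extract_tissue_timecourses(bold, array(0.5, dims),
                                       threshold = 0, erosion_voxels = 0)
  expect_equal(ncol(all_in$timecourses), prod(dims))

  # 3x3x3 block of probability 1: one erosion leaves only the centre
  pm <- array(0, dims); pm[3:5, 3:5, 3:5] <- 1
  ex <- extract_tissue_timecourses(bold, pm, threshold = 0.9,
                                   erosion_voxels = 1)
  expect_equal(sum(ex$mask), 1L)
  expect_true(ex$mask[4, 4, 4])
  expect_equal(ex$timecourses[, 1], bold[4, 4, 4, ])

  expect_error(extract_tissue_timecourses(bold, pm, threshold = 0.9,
                                          erosion_voxels = 2),
               "empty after threshold 0.9 and 2")
  expect_error(extract_tissue_timecourses(bold, array(1.5, dims)), "\\[0, 1\\]")
})

test_that("PCA blocks contain the mean plus orthogonal, ordered components", {
  set.seed(5)
  base <- sin(2 * pi * (1:100) / 25)
  tc <- matrix(base, 100, 40) + matrix(rnorm(4000, sd = 0.01), 100)
  b <- pca_block(tc, 5, "WM")
  expect_equal(ncol(b$columns), 6L)
  expect_gt(abs(cor(b$columns[, 2], base)), 0.99)   # PC1 recovers the source

  pcs <- b$columns[, -1]
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-9)  # mutually orthogonal
  expect_true(all(diff(diag(gram)) <= 1e-9))        # variance-ordered

  expect_error(pca_block(tc[, 1:4], 5), "at least 6 voxels")
})

test_that("the RP block passes the six parameters through unchanged", {
  rp <- matrix(rnorm(600), 100, 6)
  b <- rp_block(rp)
  expect_equal(unname(b$columns), unname(rp))
  expect_error(rp_block(rp[, 1:5]), "exactly 6")
  rp[, 1] <- 1                                # constant column retained
  expect_equal(unname(rp_block(rp)$columns[, 1]), rep(1, 100))
})

test_that("orthogonalisation removes polynomial content and drops spanned columns", {
  n <- 80
  poly <- polynomial_block(n)
  t_norm <- seq(-1, 1, length.out = n)
  sine <- sin(2 * pi * (1:n) / 10)
  col <- 2 * t_norm + sine

  out <- orthogonalise(list(regressor_block("WM", cbind(col))), poly)
  got <- out[[1]]$columns[, 1]
  expect_lt(max(abs(crossprod(poly$columns, got))), 1e-9)
  # Gram-Schmidt oracle: the sinusoid minus its own polynomial projection
  q <- qr.Q(qr(poly$columns))
  expect_equal(got, drop(sine - q %*% (t(q) %*% sine)), tolerance = 1e-9)

  # an already-orthogonal column is a fixed point
  ortho <- drop(sine - q %*% (t(q) %*% sine))
  out2 <- orthogonalise(list(regressor_block("CSF", cbind(ortho))), poly)
  expect_equal(out2[[1]]$columns[, 1], ortho, tolerance = 1e-9)

  # a column inside the polynomial span is dropped with a warning
  expect_warning(
    out3 <- orthogonalise(list(regressor_block("RP",
      cbind(t_norm^2, sine))), poly),
    "dropped 1 column")
  expect_equal(ncol(out3[[1]]$columns), 1L)

  # Detr and ExplTrend blocks pass through untouched
  tr <- regressor_block("ExplTrend", cbind(t_norm + sine))
  expect_identical(orthogonalise(list(tr), poly)[[1]]$columns, tr$columns)
})

test_that("regress_out matches the normal equations and is a projection", {
  set.seed(6)
  n <- 50
  x <- cbind(1, matrix(rnorm(n * 3), n))
  y <- rnorm(n)
  dm <- design_matrix(list(regressor_block("WM", x)))
  res <- regress_out(y, dm)
  expect_equal(res, drop(normal_equations_residual(y, x)), tolerance = 1e-9)
  expect_lt(max(abs(crossprod(x, res))) / sqrt(sum(y^2)), 1e-8)

  # y in span(X) -> zero; y orthogonal to X -> unchanged
  expect_lt(max(abs(regress_out(x %*% c(1, 2, 3, 4), dm))), 1e-9)
  y_perp <- res
  expect_equal(regress_out(y_perp, dm), y_perp, tolerance = 1e-9)

  # idempotent and linear
  y2 <- rnorm(n)
  expect_equal(regress_out(regress_out(y2, dm), dm), regress_out(y2, dm),
               tolerance = 1e-10)
  expect_equal(regress_out(2 * y + 3 * y2, dm),
               2 * regress_out(y, dm) + 3 * regress_out(y2, dm),
               tolerance = 1e-10)

  expect_error(design_matrix(list(regressor_block("WM", cbind(x, x[, 2])))),
               "rank deficient")
})

test_that("Fourier-domain regression reproduces time-domain residuals", {
  set.seed(7)
  n <- 32
  u <- unitary_dft(n)
  expect_equal(Mod(u %*% Conj(t(u))), diag(n), tolerance = 1e-12)

  # constant regressor zeroes exactly the DC component
  y <- rnorm(n)
  yf <- u %*% y
  resf <- regress_fourier(yf, u %*% cbind(rep(1, n)))
  expect_lt(Mod(resf[1]), 1e-10)
  expect_equal(Mod(resf[-1]), Mod(yf[-1]), tolerance = 1e-10)

  # general design: inverse transform of the Fourier residual equals the
  # time-domain residual
  x <- cbind(1, seq(-1, 1, length.out = n), rnorm(n))
  resf <- regress_fourier(u %*% y, u %*% x)
  back <- Re(Conj(t(u)) %*% resf)
  expect_equal(drop(back),
               regress_out(y, list(regressor_block("WM", x))),
               tolerance = 1e-9)

  # a linear trend mixes frequencies: in-band magnitudes change even for a
  # tone plus trend input
  tone <- exact_tone(n, 5)
  y2 <- tone + 3 * seq(-1, 1, length.out = n)
  resf2 <- regress_fourier(u %*% y2, u %*% cbind(1, seq(-1, 1, length.out = n)))
  mags <- Mod(resf2)[2:(n / 2)]
  tone_mags <- Mod(u %*% tone)[2:(n / 2)]
  expect_gt(max(abs(mags - tone_mags)), 1e-6)
})

test_that("phase-randomised surrogates keep spectra and correlations", {
  set.seed(8)
  n <- 100
  blocks <- list(
    regressor_block("WM", matrix(rnorm(2 * n), n)),
    regressor_block("RP", matrix(rnorm(2 * n), n))
  )
  sets <- phase_randomise(blocks, n_repetitions = 25)
  expect_length(sets, 25)
  expect_length(sets[[1]], 2)
  expect_equal(dim(sets[[13]][[2]]$columns), c(n, 2L))

  orig <- do.call(cbind, lapply(blocks, `[[`, "columns"))
  for (rep_i in c(1, 12, 25)) {
    sur <- do.call(cbind, lapply(sets[[rep_i]], `[[`, "columns"))
    expect_true(is.numeric(sur) && all(is.finite(sur)))  # exactly real
    expect_equal(Mod(mvfft(sur)), Mod(mvfft(orig)), tolerance = 1e-9)
    expect_equal(cor(sur), cor(orig), tolerance = 1e-6)
  }
  # different repetitions differ
  expect_false(isTRUE(all.equal(sets[[1]][[1]]$columns,
                                sets[[2]][[1]]$columns)))
})

test_that("lag-one CCA recovers an injected shared drift", {
  set.seed(9)
  n <- 200; v <- 100
  drift <- generate_band_limited_signal(n, 2, c(0.004, 0.02), 1)
  x <- outer(drift, runif(v, 0.5, 1.5)) + matrix(rnorm(n * v), n)
  tr <- exploratory_trends(x, n_trends = 4)
  expect_equal(dim(tr$columns), c(n, 4L))
  expect_gt(abs(cor(tr$columns[, 1], drift)), 0.9)
  expect_true(all(diff(attr(tr, "autocorrelations")) <= 1e-12))

  # pure white noise: no strongly autocorrelated trend at N = 400
  set.seed(10)
  noise <- matrix(rnorm(400 * 100), 400)
  tr0 <- exploratory_trends(noise)
  expect_lt(max(abs(attr(tr0, "autocorrelations"))), 0.5)

  expect_error(exploratory_trends(matrix(rnorm(40 * 30), 40), n_trends = 4),
               "n_trends")
})
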