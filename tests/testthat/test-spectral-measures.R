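# Spectral measures: spectra, ALFF/fALFF/hfALFF, standardisation,
# smoothing, bias-field handling.

test_that("one-sided spectra match a direct-summation DFT", {
  # constant series: only DC
  sp <- compute_spectrum(rep(3, 64), 2)
  expect_equal(sp$magnitudes[1], 64 * 3)
  expect_lt(max(sp$magnitudes[-1]), 1e-9)
  expect_equal(sp$frequencies[1], 0)
  expect_equal(sp$frequencies[length(sp$frequencies)], 0.25)  # Nyquist, TR 2

  # exact tone: single nonzero bin
  x <- exact_tone(64, k = 5)
  sp <- compute_spectrum(x, 2)
  expect_equal(which.max(sp$magnitudes), 6L)   # bin k=5 is element 6
  expect_lt(sort(sp$magnitudes, decreasing = TRUE)[2], 1e-9)

  # odd length vs naive DFT
  set.seed(33)
  y <- rnorm(33)
  sp <- compute_spectrum(y, 1.5)
  expect_length(sp$magnitudes, 17)
  expect_equal(sp$magnitudes, naive_dft_magnitudes(y),
               tolerance = 1e-9)

  expect_error(compute_spectrum(c(1, NA, 3, 4), 2), "non-finite")
  expect_error(compute_spectrum(rep(1, 3), 2), "length >= 4")
})

test_that("ALFF sums in-band magnitudes and is linear in amplitude", {
  sp0 <- compute_spectrum(numeric(64), 2)
  expect_equal(alff(sp0), 0)

  x <- exact_tone(128, k = 10)              # f = 10/256 ~ 0.039 Hz, in band
  sp <- compute_spectrum(x, 2)
  expect_equal(alff(sp), 128 / 2, tolerance = 1e-9)  # |Z| = N*A/2

  set.seed(1)
  y <- rnorm(128)
  expect_equal(alff(compute_spectrum(2 * y, 2)),
               2 * alff(compute_spectrum(y, 2)), tolerance = 1e-12)

  expect_error(alff(compute_spectrum(y, 2), band = c(0.0001, 0.0005)),
               "no DFT bin")
})

test_that("fALFF and hfALFF follow the two-bin arithmetic oracles", {
  n <- 256
  # all power inside the band, demeaned
  set.seed(2)
  x <- generate_band_limited_signal(n, 2, c(0.02, 0.08), 1)
  expect_equal(falff(compute_spectrum(x, 2)), 1, tolerance = 1e-12)
  expect_equal(hfalff(compute_spectrum(x, 2)), 1, tolerance = 1e-12)

  # pure tone strictly above the band
  hi <- exact_tone(n, k = 80)               # 80/512 = 0.156 Hz
  expect_equal(falff(compute_spectrum(hi, 2)), 0, tolerance = 1e-12)

  # in-band tone (magnitude 3) + out-of-band tone (magnitude 1) -> 0.75
  two <- 3 * exact_tone(n, k = 10) + 1 * exact_tone(n, k = 80)
  expect_equal(falff(compute_spectrum(two, 2)), 0.75, tolerance = 1e-12)

  # power below 0.01 Hz and inside band, split 1:1 -> fALFF 0.5, hfALFF 1
  low <- exact_tone(n, k = 2)               # 2/512 ~ 0.0039 Hz < 0.01
  mix <- low + exact_tone(n, k = 10)
  expect_equal(falff(compute_spectrum(mix, 2)), 0.5, tolerance = 1e-12)
  expect_equal(hfalff(compute_spectrum(mix, 2)), 1, tolerance = 1e-12)

  expect_error(falff(compute_spectrum(rep(5, n), 2)), "zero")
  expect_true(is.na(falff(compute_spectrum(rep(5, n), 2),
                          na_on_zero = TRUE)))
})

test_that("0 <= fALFF <= hfALFF <= 1 for random series", {
  set.seed(4)
  for (i in 1:50) {
    sp <- compute_spectrum(rnorm(100, sd = runif(1, 0.1, 10)), 2)
    f <- falff(sp); hf <- hfalff(sp)
    expect_gte(f, 0); expect_gte(hf, f); expect_lte(hf, 1)
  }
})

test_that("standardisation fixes the in-mask mean to 1 and is idempotent", {
  dims <- c(4, 4, 2)
  mask <- array(TRUE, dims)
  m7 <- fluctuation_map(array(7, dims), "alff", c(0.01, 0.1), mask)
  s <- standardise_map(m7)
  expect_equal(as.vector(s$values), rep(1, 32))
  expect_true(s$standardised)

  vals <- array(0, dims); vals[1:3] <- c(1, 2, 3)
  mask3 <- array(FALSE, dims); mask3[1:3] <- TRUE
  s3 <- standardise_map(fluctuation_map(vals, "alff", c(0.01, 0.1), mask3))
  expect_equal(s3$values[1:3], c(0.5, 1, 1.5))
  expect_equal(s3$values[4], 0)             # out-of-mask zeroed

  expect_identical(standardise_map(s3)$values, s3$values)

  zero <- fluctuation_map(array(0, dims), "alff", c(0.01, 0.1), mask)
  expect_error(standardise_map(zero), "positive")
})

test_that("Gaussian smoothing matches the closed-form separable kernel", {
  dims <- c(15, 15, 15)
  vals <- array(0, dims); vals[8, 8, 8] <- 1
  mask <- array(TRUE, dims)
  m <- fluctuation_map(vals, "alff", c(0.01, 0.1), mask)

  expect_identical(gaussian_smooth(m, 0)$values, vals)   # identity

  fwhm <- 6; vox <- c(3, 3, 3)
  sm <- gaussian_smooth(m, fwhm, vox)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / 3
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-0.5 * ((-r):r / sigma)^2); k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  idx <- (8 - r):(8 + r)
  expect_equal(sm$values[idx, idx, idx], expected, tolerance = 1e-12)
  expect_equal(sum(sm$values), 1, tolerance = 1e-12)     # mass conserved

  u <- fluctuation_map(array(2, dims), "falff", c(0.01, 0.1), mask)
  su <- gaussian_smooth(u, 6, vox)
  expect_equal(as.vector(su$values), rep(2, prod(dims)), tolerance = 1e-12)

  expect_error(gaussian_smooth(m, -1), ">= 0")
})

test_that("bias correction rescales ALFF but leaves fALFF untouched", {
  cfg <- tiny_config()
  ds <- generate_subject(cfg, 1, 1)
  brain <- ds$masks$gm | ds$masks$wm | ds$masks$csf

  expect_identical(apply_bias_correction(ds$bold, array(1, cfg$grid_dims)),
                   ds$bold)

  halved <- apply_bias_correction(ds$bold, array(2, cfg$grid_dims))
  a0 <- compute_fluctuation_map(ds$bold, 2, "alff", mask = brain)
  a1 <- compute_fluctuation_map(halved, 2, "alff", mask = brain)
  expect_equal(a1$values[brain], a0$values[brain] / 2, tolerance = 1e-12)

  set.seed(9)
  g <- generate_bias_field(cfg$grid_dims, c(0.5, 2))
  f0 <- compute_fluctuation_map(ds$bold, 2, "falff", mask = brain)
  f1 <- compute_fluctuation_map(apply_bias_correction(ds$bold, g), 2,
                                "falff", mask = brain)
  expect_equal(f1$values[brain], f0$values[brain], tolerance = 1e-9)

  expect_error(apply_bias_correction(ds$bold, array(0, cfg$grid_dims)),
               "positive")
})
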