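# Synthetic BOLD generator: drift, band-limited signals, bias fields,
# subject/group composition and their ground truth.

test_that("polynomial drift matches pointwise evaluation on [-1, 1]", {
  expect_equal(generate_drift(100, c(5, 0, 0)), rep(5, 100))

  lin <- generate_drift(100, c(0, 1, 0))
  expect_equal(lin[1], -1)
  expect_equal(lin[100], 1)
  expect_true(all(diff(lin) > 0))

  n <- 128
  coeffs <- c(1, 2, 3)
  got <- generate_drift(n, coeffs)
  t_norm <- seq(-1, 1, length.out = n)
  expected <- numeric(n)
  for (i in seq_len(n))          # independent loop evaluation
    expected[i] <- coeffs[1] + coeffs[2] * t_norm[i] + coeffs[3] * t_norm[i]^2
  expect_equal(got, expected, tolerance = 1e-12)

  expect_error(generate_drift(100, c(1, NA, 0)), "finite")
  expect_error(generate_drift(1, c(1, 1, 1)))
})

test_that("band-limited signals are spectrally confined with the target SD", {
  set.seed(7)
  x <- generate_band_limited_signal(200, 2, c(0.01, 0.1), sd = 1)
  sp <- compute_spectrum(x, 2)
  out_of_band <- sp$frequencies > 0.1 + 1e-12
  expect_lt(max(sp$magnitudes[out_of_band]), 1e-9 * max(sp$magnitudes))
  expect_equal(sd(x), 1, tolerance = 1e-10)   # rescaled exactly
  expect_equal(mean(x), 0, tolerance = 1e-10)

  expect_identical(generate_band_limited_signal(200, 2, c(0.01, 0.1), 0),
                   numeric(200))

  set.seed(8)
  y <- generate_band_limited_signal(256, 2, c(0.04, 0.06), sd = 2)
  expect_equal(falff(compute_spectrum(y, 2), band = c(0.04, 0.06)), 1,
               tolerance = 1e-12)

  expect_error(generate_band_limited_signal(64, 2, c(0.0001, 0.0005), 1),
               "no DFT bin")
})

test_that("bias fields are smooth, bounded and RNG-reproducible", {
  set.seed(1)
  flat <- generate_bias_field(c(8, 8, 8), range = c(1, 1))
  expect_equal(as.vector(flat), rep(1, 512))

  set.seed(2)
  g <- generate_bias_field(c(16, 16, 16), range = c(0.5, 2))
  expect_true(all(g >= 0.5 & g <= 2))

  set.seed(3); g1 <- generate_bias_field(c(16, 16, 16), c(0.5, 2))
  set.seed(3); g2 <- generate_bias_field(c(16, 16, 16), c(0.5, 2))
  set.seed(4); g3 <- generate_bias_field(c(16, 16, 16), c(0.5, 2))
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))

  expect_error(generate_bias_field(c(8, 8, 8), c(0, 1)), "positive")
})

test_that("tissue masks are disjoint, non-empty, and need a minimum grid", {
  masks <- tissue_masks(c(16, 16, 10))
  expect_true(all(vapply(masks, sum, 0L) > 0))
  expect_false(any(masks$gm & masks$wm))
  expect_false(any(masks$gm & masks$csf))
  expect_false(any(masks$wm & masks$csf))
  expect_error(tissue_masks(c(6, 6, 6)), "grid too small")
})

test_that("with all noise terms off, non-GM voxel time courses are constant", {
  cfg <- tiny_config(thermal_noise_sd = 0, motion_coupling = 0,
                     physio_amp_cv = 0, physio_session_cv = 0,
                     physio_coupling = c(gm = 0, wm = 0, csf = 0),
                     drift_coeff_sd = c(0, 0, 0), session_drift_jitter = 0,
                     slow_drift_sd = 0, bias_field_range = c(1, 1))
  ds <- generate_subject(cfg, 1, 1)
  wm_tc <- apply(ds$bold, 4, function(v) v[ds$masks$wm])
  expect_lt(max(abs(wm_tc - cfg$baseline)), 1e-9)
})

test_that("without a GM signal, GM and WM voxels share one distribution", {
  cfg <- tiny_config(gm_lff_sd = 0, n_timepoints = 128,
                     physio_coupling = c(gm = 1, wm = 1, csf = 1),
                     drift_tissue_weight = c(gm = 1, wm = 1, csf = 1),
                     drift_profile_range = c(1, 1), motion_coupling = 0,
                     slow_drift_sd = 0)
  ds <- generate_subject(cfg, 1, 1)
  flat <- matrix(ds$bold, ncol = dim(ds$bold)[4])
  # variance of demeaned, bias-removed time courses should match in law
  v <- apply(flat / as.vector(ds$bias_field), 1, var)
  ratio <- mean(v[ds$masks$gm]) / mean(v[ds$masks$wm])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
  expect_equal(max(ds$ground_truth$amplitude_map), 0)
})

test_that("regressing the true nuisance out of a WM voxel leaves thermal noise", {
  cfg <- tiny_config(n_timepoints = 256, grid_dims = c(10, 10, 10))
  ds <- generate_subject(cfg, 1, 1)
  gt <- ds$ground_truth
  flat <- matrix(ds$bold, ncol = 256)
  wm_idx <- which(ds$masks$wm)
  x <- cbind(polynomial_block(256)$columns, gt$physio, gt$motion_signal)
  dm <- design_matrix(list(regressor_block("RP", x)))
  set.seed(11)
  resid_var <- vapply(sample(wm_idx, 30), function(i) {
    var(regress_out(flat[i, ] / ds$bias_field[i], dm))
  }, 0)
  expect_equal(mean(resid_var), cfg$thermal_noise_sd^2, tolerance = 0.15)
})

test_that("groups are structured by subject and session and reproducible", {
  cfg <- tiny_config()
  set.seed(99)
  g1 <- generate_group(cfg)
  expect_length(g1$subjects, 3)
  expect_true(all(vapply(g1$subjects, length, 0L) == 2))

  g2 <- generate_group(cfg)
  expect_identical(g1, g2)     # deterministic in the config alone

  g3 <- generate_group(tiny_config(rng_seed = 43L))
  expect_false(identical(g1$subjects[[1]][[1]]$bold,
                         g3$subjects[[1]][[1]]$bold))

  # subject-level parameters constant across sessions
  s <- g1$subjects[[2]]
  expect_identical(s[[1]]$ground_truth$drift_coeffs_subject,
                   s[[2]]$ground_truth$drift_coeffs_subject)
  expect_identical(s[[1]]$bias_field, s[[2]]$bias_field)
  expect_false(identical(s[[1]]$ground_truth$drift_coeffs_session,
                         s[[2]]$ground_truth$drift_coeffs_session))

  expect_error(generate_group(simulation_config(n_subjects = 1)),
               "n_subjects >= 2")
})

test_that("fitted linear-trend coefficients recover the configured spread", {
  cfg <- simulation_config(n_subjects = 20, n_sessions = 1,
                           n_timepoints = 128, grid_dims = c(10, 10, 10),
                           drift_coeff_sd = c(0, 2, 0),
                           drift_severity_cv = 0, session_drift_jitter = 0,
                           drift_profile_range = c(1, 1),
                           drift_tissue_weight = c(gm = 1, wm = 1, csf = 1),
                           slow_drift_sd = 0, motion_coupling = 0,
                           physio_amp_cv = 0, physio_session_cv = 0,
                           bias_field_range = c(1, 1), rng_seed = 5L)
  group <- generate_group(cfg)
  poly <- polynomial_block(128)$columns
  wm <- group$subjects[[1]][[1]]$masks$wm
  c1_hat <- vapply(group$subjects, function(s) {
    tc <- rowMeans(t(matrix(s[[1]]$bold, ncol = 128))[, which(wm)])
    qr.coef(qr(poly), tc)[2]
  }, 0)
  expect_equal(var(c1_hat), 4, tolerance = 0.3 * 4)
})
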