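# Synthetic multi-subject, multi-session BOLD generator.
#
# All randomness is drawn from R's global RNG; generate_subject() and
# generate_group() seed it deterministically from the configuration, so a
# fixed config (including rng_seed) yields bit-identical groups.

# Deterministic sub-seed for (subject, session, stream); kept below 2^31.
.derived_seed <- function(seed, subject = 0L, session = 0L, stream = 0L) {
  s <- (as.double(seed) + 104729 * subject + 7919 * session +
          15485863 * stream) %% 2147483629
  as.integer(s)
}

#' Polynomial drift time course
#'
#' Evaluates `c0 + c1 * t + c2 * t^2` on a time axis normalised to
#' `[-1, 1]`, the parameterisation used throughout the package for the
#' constant/linear/quadratic trend basis (it keeps the three regressors
#' well-conditioned).
#'
#' @param n_timepoints series length (>= 2).
#' @param coeffs numeric vector of three finite coefficients
#'   (constant, linear, quadratic).
#' @return Numeric vector of length `n_timepoints`.
#' @export
#' @examples
#' generate_drift(5, c(1, 2, 3))
generate_drift <- function(n_timepoints, coeffs) {
  if (n_timepoints < 2) stop("n_timepoints must be >= 2")
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != 3L || any(!is.finite(coeffs)))
    stop("coeffs must be three finite values (constant, linear, quadratic)")
  t_norm <- seq(-1, 1, length.out = n_timepoints)
  coeffs[1] + coeffs[2] * t_norm + coeffs[3] * t_norm^2
}

# DFT bin indices (1 .. floor(N/2)) whose frequencies fall inside [low, high].
.band_bins <- function(n, tr, band) {
  k <- seq_len(n %/% 2)
  f <- k / (n * tr)
  tol <- 1e-12
  k[f >= band[1] - tol & f <= band[2] + tol]
}

# N x V matrix of independent band-limited series, each with unit sample SD.
# `exponent` > 0 weights the expected magnitude of bin k by f_k^-exponent
# (a 1/f-type spectral envelope inside the band).
.band_limited_matrix <- function(n, tr, band, n_series, exponent = 0) {
  bins <- .band_bins(n, tr, band)
  if (length(bins) == 0L)
    stop(sprintf(
      "no DFT bin falls inside the band %g-%g Hz: bin spacing is 1/(N*TR) = %g Hz",
      band[1], band[2], 1 / (n * tr)))
  z <- matrix(0 + 0i, nrow = n, ncol = n_series)
  for (k in bins) {
    w <- if (exponent > 0) k^-exponent else 1
    if (2L * k == n) {           # Nyquist bin of an even-length series: real
      z[k + 1L, ] <- w * rnorm(n_series)
    } else {
      coef <- w * complex(real = rnorm(n_series), imaginary = rnorm(n_series))
      z[k + 1L, ] <- coef
      z[n - k + 1L, ] <- Conj(coef)
    }
  }
  x <- Re(mvfft(z, inverse = TRUE)) / n
  s <- apply(x, 2L, sd)
  s[s == 0] <- 1
  sweep(x, 2L, s, "/")
}

#' Band-limited random signal
#'
#' Zero-mean Gaussian series whose one-sided DFT magnitudes are nonzero only
#' at bins inside `band`; the sample standard deviation is rescaled to `sd`
#' exactly.  Uses the current state of R's RNG.
#'
#' @param n_timepoints series length.
#' @param tr_seconds sampling interval (s).
#' @param band `c(low, high)` in Hz, within `(0, Nyquist]`.
#' @param sd target sample standard deviation; 0 yields an all-zero series.
#' @return Numeric vector of length `n_timepoints`.
#' @export
generate_band_limited_signal <- function(n_timepoints, tr_seconds, band, sd) {
  stopifnot(n_timepoints >= 4, tr_seconds > 0, length(band) == 2L)
  nyq <- 1 / (2 * tr_seconds)
  if (band[1] <= 0 || band[1] >= band[2] || band[2] > nyq + 1e-12)
    stop("band must satisfy 0 < low < high <= Nyquist")
  if (!is.finite(sd) || sd < 0) stop("sd must be finite and >= 0")
  if (sd == 0) return(numeric(n_timepoints))
  drop(.band_limited_matrix(n_timepoints, tr_seconds, band, 1L)) * sd
}

# Linear upsampling of a vector to length `n_out` (used axis-wise below).
.upsample <- function(v, n_out) {
  if (length(v) == 1L) return(rep(v, n_out))
  approx(x = seq(0, 1, length.out = length(v)), y = v,
         xout = seq(0, 1, length.out = n_out))$y
}

#' Smooth multiplicative bias field
#'
#' A low-spatial-frequency positive 3D gain volume: a coarse grid of uniform
#' variates trilinearly upsampled to `grid_dims` and rescaled to lie in
#' `range`.  Uses the current state of R's RNG.
#'
#' @param grid_dims integer vector of 3 voxel counts.
#' @param range `c(min, max)` gain with `0 < min <= max`; `min == max`
#'   yields a uniform field.
#' @param coarse_dims resolution of the underlying random grid.
#' @return 3D array of gains in `[min, max]`.
#' @export
generate_bias_field <- function(grid_dims, range = c(0.8, 1.2),
                                coarse_dims = c(4L, 4L, 3L)) {
  stopifnot(length(grid_dims) == 3L, length(range) == 2L)
  if (range[1] <= 0) stop("bias field minimum gain must be positive")
  if (range[1] > range[2]) stop("range must be c(min, max) with min <= max")
  coarse <- array(runif(prod(coarse_dims)), dim = coarse_dims)
  # upsample one axis at a time
  up1 <- apply(coarse, c(2, 3), .upsample, n_out = grid_dims[1])
  dim(up1) <- c(grid_dims[1], coarse_dims[2], coarse_dims[3])
  up2 <- aperm(apply(up1, c(1, 3), .upsample, n_out = grid_dims[2]),
               c(2, 1, 3))
  dim(up2) <- c(grid_dims[1], grid_dims[2], coarse_dims[3])
  up3 <- aperm(apply(up2, c(1, 2), .upsample, n_out = grid_dims[3]),
               c(2, 3, 1))
  dim(up3) <- grid_dims
  lo <- min(up3); hi <- max(up3)
  if (hi > lo) {
    range[1] + (up3 - lo) / (hi - lo) * (range[2] - range[1])
  } else {
    array(mean(range), dim = grid_dims)
  }
}

# Nested-box tissue geometry: CSF core, WM shell, GM rind, inside a brain box.
.centre_box <- function(dims, frac) {
  lo <- pmax(1L, floor(dims * (1 - frac) / 2) + 1L)
  hi <- pmin(dims, lo + pmax(1L, round(dims * frac)) - 1L)
  m <- array(FALSE, dim = dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Tissue compartment masks for the synthetic grid
#'
#' Three pairwise-disjoint boolean volumes: a central CSF box, a WM shell
#' around it and a GM rind around the WM, occupying roughly the central
#' 25/50/75% of each grid axis.
#'
#' @param grid_dims integer vector of 3 voxel counts (each >= 8).
#' @return Named list of logical arrays `gm`, `wm`, `csf`.
#' @export
tissue_masks <- function(grid_dims) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 8L))
    stop("grid too small to host three disjoint tissue compartments: ",
         "need at least 8 voxels per axis")
  b_gm <- .centre_box(grid_dims, 0.80)
  b_wm <- .centre_box(grid_dims, 0.60)
  b_csf <- .centre_box(grid_dims, 0.30)
  masks <- list(gm = b_gm & !b_wm, wm = b_wm & !b_csf, csf = b_csf)
  if (any(vapply(masks, sum, 0L) == 0L))
    stop("grid too small to host three disjoint tissue compartments")
  masks
}

# Simulated head motion: slow random walks plus occasional spikes.  The
# returned list separates true motion (which couples into the data) from
# the measured realignment parameters (true motion plus frame-to-frame
# estimation noise), as produced by any realignment algorithm.
.simulate_rp <- function(n, spike_prob = 0.3, spike_sd = 0.05,
                         ar_coef = 0.97) {
  step_sd <- c(rep(0.02, 3), rep(2e-4, 3))
  # mean-reverting (AR(1)) position wander: subjects drift and re-settle,
  # so head position carries little net trend over a run
  true_rp <- vapply(step_sd, function(s)
    as.numeric(stats::filter(rnorm(n, 0, s), ar_coef, method = "recursive")) +
      rnorm(n, 0, 1.5 * s), numeric(n))
  if (runif(1) < spike_prob) {    # occasional brief head jerk
    at <- sample.int(n, 1L)
    true_rp[at, 1:3] <- true_rp[at, 1:3] + rnorm(3, 0, spike_sd)
  }
  measured <- true_rp + vapply(step_sd * 0.2, function(s) rnorm(n, 0, s),
                               numeric(n))
  colnames(true_rp) <- colnames(measured) <-
    c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  list(true = true_rp, measured = measured)
}

# Deterministic edge-weighted spatial profile: motion artefacts are
# strongest at tissue boundaries far from the rotation centre.
.edge_profile <- function(dims) {
  ctr <- (dims + 1) / 2
  r <- sqrt(outer(outer((seq_len(dims[1]) - ctr[1])^2 / ctr[1]^2,
                        (seq_len(dims[2]) - ctr[2])^2 / ctr[2]^2, "+"),
                  (seq_len(dims[3]) - ctr[3])^2 / ctr[3]^2, "+"))
  0.5 + r / max(r)
}

# Unit-SD motion nuisance signal: fixed low-order combination of the RPs.
.motion_signal <- function(rp) {
  z <- scale(rp)
  z[is.na(z)] <- 0
  w <- c(1, 0.8, 0.6, 1, 0.8, 0.6)
  m <- drop(z %*% w)
  s <- sd(m)
  if (s > 0) m / s else m
}

# Per-subject parameters, deterministic in (config, subject_index).
# A common lognormal "drift severity" scales both the polynomial scanner
# drift and the slow grey-matter fluctuation, so a subject's low-frequency
# contamination is coherent across components.
.subject_params <- function(config, subject_index) {
  set.seed(.derived_seed(config$rng_seed, subject_index, 0L, 2L))
  cv <- config$drift_severity_cv
  severity <- exp(rnorm(1, 0, cv) - cv^2 / 2)
  list(
    severity = severity,
    drift_coeffs = severity * rnorm(3, 0, 1) * config$drift_coeff_sd,
    slow_amp = severity * config$slow_drift_sd,
    physio_amps = 1 + rnorm(length(config$physio_freqs), 0,
                            config$physio_amp_cv),
    amp_factor = 1 + rnorm(1, 0, 0.1),
    bias_field = generate_bias_field(config$grid_dims,
                                     config$bias_field_range),
    drift_profile = generate_bias_field(config$grid_dims,
                                        config$drift_profile_range),
    slow_profiles = lapply(seq_len(config$n_slow_components), function(j)
      generate_bias_field(config$grid_dims, config$drift_profile_range)),
    physio_profile = generate_bias_field(config$grid_dims,
                                         config$drift_profile_range)
  )
}

# Group-level GM amplitude pattern, deterministic in the config seed.
.group_amplitude_pattern <- function(config) {
  set.seed(.derived_seed(config$rng_seed, 0L, 0L, 1L))
  array(runif(prod(config$grid_dims), 0.75, 1.25), dim = config$grid_dims)
}

#' Generate one synthetic subject/session data set
#'
#' Composes the generative model described in [simulation_config()] for one
#' scanning session.  Subject-level parameters (drift coefficients, slow-
#' fluctuation amplitude, physiological amplitudes, amplitude-map factor and
#' bias field) are shared across that subject's sessions; session-level
#' realisations (signal and noise draws, realignment parameters, drift
#' jitter) differ.
#'
#' @param config a [simulation_config()] object.
#' @param subject_index subject number (1-based).
#' @param session_index session number (1-based).
#' @param keep_components if `TRUE`, store the noise-free nuisance
#'   components (per-voxel slow fluctuations, physiological and motion
#'   signals added to each voxel) in `ground_truth$components` for
#'   parameter-recovery tests.  Off by default to save memory.
#' @return An object of class `subject_dataset`: a list with `bold`
#'   (4D array, grid x N), `masks` (list of disjoint logical arrays `gm`,
#'   `wm`, `csf`), `realignment_params` (N x 6 matrix), `bias_field`,
#'   `ground_truth`, `tr_seconds`, `subject_index`, `session_index`.
#' @export
generate_subject <- function(config, subject_index = 1L, session_index = 1L,
                             keep_components = FALSE) {
  validate_sim_config(config)
  dims <- config$grid_dims
  n <- config$n_timepoints
  masks <- tissue_masks(dims)
  amp_pattern <- .group_amplitude_pattern(config)
  sp <- .subject_params(config, subject_index)

  brain <- masks$gm | masks$wm | masks$csf
  idx <- which(brain)
  v_brain <- length(idx)
  tissue <- character(v_brain)
  tissue[masks$gm[brain]] <- "gm"
  tissue[masks$wm[brain]] <- "wm"
  tissue[masks$csf[brain]] <- "csf"

  set.seed(.derived_seed(config$rng_seed, subject_index, session_index, 3L))

  # session-level drift: subject coefficients plus small jitter
  drift_coeffs <- sp$drift_coeffs + sp$severity * rnorm(3, 0, 1) *
    config$session_drift_jitter * config$drift_coeff_sd
  drift <- generate_drift(n, drift_coeffs)

  # shared physiological components: unit-SD narrowband signals around the
  # centre frequencies (heart rate and breathing depth wander within a run)
  nyq <- 1 / (2 * config$tr_seconds)
  physio <- vapply(seq_along(config$physio_freqs), function(j) {
    f <- config$physio_freqs[j]
    half <- config$physio_bandwidth_hz / 2
    pband <- c(max(f - half, 1 / (n * config$tr_seconds)), min(f + half, nyq))
    drop(.band_limited_matrix(n, config$tr_seconds, pband, 1L))
  }, numeric(n))

  rp_sim <- .simulate_rp(n)
  rp <- rp_sim$measured
  motion <- .motion_signal(rp_sim$true)
  session_physio_amps <- sp$physio_amps *
    (1 + rnorm(length(config$physio_freqs), 0, config$physio_session_cv))

  profile <- sp$drift_profile[brain]
  m <- matrix(config$baseline, nrow = n, ncol = v_brain)
  # polynomial drift: scanner drift everywhere, strongly amplified in CSF
  # (pulsatile partial-volume drift), modulated by the spatial profile
  drift_w <- unname(config$drift_tissue_weight[tissue])
  m <- m + outer(drift, profile * drift_w)

  # shared grey-matter slow fluctuations: several independent slow
  # processes with steep spectra straddling the lower band edge, each with
  # its own smooth spatial profile; absent from WM/CSF
  gm_cols <- which(tissue == "gm")
  n_slow <- config$n_slow_components
  slow_tc <- matrix(0, nrow = n, ncol = n_slow)
  if (sp$slow_amp > 0 && length(gm_cols) > 0) {
    slow_tc <- .band_limited_matrix(n, config$tr_seconds,
                                    config$slow_drift_band, n_slow,
                                    exponent = 1)
    amp_j <- sp$slow_amp / sqrt(n_slow)
    gm_vox <- which(brain)[gm_cols]
    for (j in seq_len(n_slow)) {
      pj <- sp$slow_profiles[[j]][gm_vox]
      m[, gm_cols] <- m[, gm_cols] + outer(amp_j * slow_tc[, j], pj)
    }
  }

  # physiological components: per-tissue (and per-component) coupling
  # modulated by a smooth subject-level spatial profile (vascular density
  # varies across the brain)
  pc <- config$physio_coupling
  physio_part <- NULL
  for (j in seq_along(config$physio_freqs)) {
    row <- if (is.matrix(pc)) pc[j, ] else pc
    kappa <- unname(row[tissue]) * sp$physio_profile[brain]
    contrib <- outer(physio[, j], kappa * session_physio_amps[j])
    if (keep_components)
      physio_part <- if (is.null(physio_part)) contrib else physio_part + contrib
    m <- m + contrib
  }

  # motion-coupled nuisance, edge-weighted (strongest at the brain edge)
  if (config$motion_coupling > 0)
    m <- m + config$motion_coupling *
      outer(motion, .edge_profile(dims)[brain])

  # band-limited GM fluctuations with ground-truth amplitude map
  amp_map <- array(0, dim = dims)
  gm_idx_in_brain <- gm_cols
  if (config$gm_lff_sd > 0 && length(gm_idx_in_brain) > 0) {
    amp_map[masks$gm] <- config$gm_lff_sd * amp_pattern[masks$gm] *
      sp$amp_factor
    # neural LFF power concentrates toward the low end of the band
    sig <- .band_limited_matrix(n, config$tr_seconds, config$lff_band,
                                length(gm_idx_in_brain),
                                exponent = config$gm_lff_exponent)
    amps <- amp_map[brain][gm_idx_in_brain]
    m[, gm_idx_in_brain] <- m[, gm_idx_in_brain] + sweep(sig, 2L, amps, "*")
  }

  if (config$thermal_noise_sd > 0)
    m <- m + matrix(rnorm(n * v_brain, 0, config$thermal_noise_sd), nrow = n)

  # multiplicative bias field, then place into the 4D volume
  gains <- sp$bias_field[brain]
  m <- sweep(m, 2L, gains, "*")
  flat <- matrix(0, nrow = prod(dims), ncol = n)
  flat[idx, ] <- t(m)
  bold <- array(flat, dim = c(dims, n))

  ground_truth <- list(
    drift = drift,
    drift_coeffs_subject = sp$drift_coeffs,
    drift_coeffs_session = drift_coeffs,
    severity = sp$severity,
    physio = physio,
    physio_amps = sp$physio_amps,
    physio_amps_session = session_physio_amps,
    amplitude_map = amp_map,
    slow_timecourses = slow_tc,
    slow_amp = sp$slow_amp,
    drift_profile = sp$drift_profile,
    motion_signal = motion
  )
  if (keep_components)
    ground_truth$components <- list(physio = physio_part)

  structure(list(
    bold = bold,
    masks = masks,
    realignment_params = rp,
    bias_field = sp$bias_field,
    ground_truth = ground_truth,
    tr_seconds = config$tr_seconds,
    lff_band = config$lff_band,
    subject_index = as.integer(subject_index),
    session_index = as.integer(session_index)
  ), class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  d <- dim(x$bold)
  cat(sprintf(
    "<subject_dataset> subject %d session %d: %dx%dx%d grid, %d time points, TR %g s\n",
    x$subject_index, x$session_index, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Generate a synthetic group
#'
#' All subjects and sessions of the configured study, deterministically from
#' `config$rng_seed`.  Subject-specific parameters are constant across each
#' subject's sessions.
#'
#' @param config a [simulation_config()] object with `n_subjects >= 2`.
#' @param keep_components passed to [generate_subject()].
#' @return An object of class `subject_group`: a list with `config` and
#'   `subjects`, where `subjects[[i]][[r]]` is the `subject_dataset` of
#'   subject `i`, session `r`.
#' @export
generate_group <- function(config, keep_components = FALSE) {
  validate_sim_config(config)
  if (config$n_subjects < 2L)
    stop("generate_group needs n_subjects >= 2")
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    sessions <- lapply(seq_len(config$n_sessions), function(r) {
      generate_subject(config, i, r, keep_components = keep_components)
    })
    names(sessions) <- sprintf("ses%02d", seq_len(config$n_sessions))
    sessions
  })
  names(subjects) <- sprintf("sub%02d", seq_len(config$n_subjects))
  structure(list(config = config, subjects = subjects),
            class = "subject_group")
}

#' @export
print.subject_group <- function(x, ...) {
  cat(sprintf("<subject_group> %d subjects x %d sessions (seed %d)\n",
              x$config$n_subjects, x$config$n_sessions, x$config$rng_seed))
  invisible(x)
}
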