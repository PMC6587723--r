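#' Simulation configuration for synthetic resting-state BOLD data
#'
#' Bundles every parameter of the synthetic generator.  The defaults describe
#' a small desk-scale study: 20 subjects scanned twice, 128 time points at
#' TR = 2 s (Nyquist 0.25 Hz, a four-minute run) on a 16 x 16 x 10 voxel
#' grid with 3 mm voxels.
#'
#' The generative model for a brain voxel time course is
#' \deqn{y(t) = g(v)\,[B + a_v s_v(t) + P_v d_s(t) + P_v S_s u_s(t)
#'   + \sum_j c_j \kappa_j p_j(t) + m\,r(t) + \epsilon_v(t)]}
#' where `g` is a smooth multiplicative bias field, `B` a constant baseline,
#' `s_v` a band-limited grey-matter fluctuation with voxelwise amplitude map
#' `a_v` (grey matter only), `d_s` a subject-level polynomial scanner drift
#' and `u_s` a shared grey-matter slow fluctuation, both modulated by a
#' smooth spatial amplitude profile `P_v` and scaled by a common subject
#' "drift severity" (`S_s` for the slow part), `p_j` shared physiological
#' components with per-tissue coupling `\kappa_j`, `r` a motion-derived
#' signal built from the realignment parameters, and `\epsilon` white
#' thermal noise.
#'
#' @param n_subjects number of subjects (>= 1; group analyses need >= 2).
#' @param n_sessions sessions per subject.
#' @param n_timepoints time points N per run (>= 16).
#' @param tr_seconds sampling interval (s); Nyquist frequency is
#'   `1/(2 * tr_seconds)`.
#' @param grid_dims integer vector of 3 voxel counts (each >= 8).
#' @param voxel_size_mm numeric vector of 3 voxel edge lengths (mm).
#' @param lff_band low-frequency band of interest `c(low, high)` in Hz;
#'   the upper edge must stay below Nyquist.
#' @param gm_lff_sd temporal SD (a.u.) of the band-limited grey-matter
#'   signal at an amplitude-map value of 1.
#' @param gm_lff_exponent spectral exponent of the grey-matter signal
#'   inside the band (magnitude envelope f^-exponent); BOLD low-frequency
#'   power concentrates toward the lower band edge.
#' @param drift_coeff_sd per-subject SDs of the constant/linear/quadratic
#'   drift coefficients (a.u.); a single value is recycled.  Scanner drift
#'   is predominantly linear, so the default weights the linear term most.
#' @param slow_drift_sd total SD (a.u.) of the shared grey-matter slow
#'   fluctuation at profile value 1 and severity 1; its 1/f spectrum
#'   straddles the lower band edge, so polynomial detrending removes its
#'   very-low-frequency mass but leaves most of its in-band tail.
#' @param n_slow_components number of independent shared slow processes,
#'   each with its own smooth spatial profile; their joint SD is
#'   `slow_drift_sd`.
#' @param slow_drift_band frequency support `c(low, high)` (Hz) of the slow
#'   fluctuation; the default straddles the 0.01 Hz band edge.
#' @param drift_severity_cv log-scale SD of the subject-level "drift
#'   severity" factor that scales both the polynomial scanner drift and the
#'   slow grey-matter fluctuation — subjects differ in how contaminated
#'   their runs are, coherently across both slow components.
#' @param drift_profile_range `c(min, max)` of the smooth spatial amplitude
#'   profile modulating the slow/drift components; spatial structure keeps
#'   map standardisation from cancelling subject drift differences.
#' @param drift_tissue_weight named vector `c(gm=, wm=, csf=)` multiplying
#'   the polynomial drift per tissue; CSF is weighted far above 1 because
#'   pulsatile partial-volume effects make its slow drift much larger than
#'   the scanner drift seen in parenchyma.
#' @param physio_freqs centre frequencies (Hz) of shared narrowband
#'   physiological components, e.g. an in-band respiratory component and an
#'   aliased cardiac one.
#' @param physio_bandwidth_hz full spectral width (Hz) of each physiological
#'   component around its centre frequency; breathing depth and heart rate
#'   wander, so the components are narrowband rather than pure tones.
#' @param physio_coupling per-tissue weights of the shared physiological
#'   components: either a named numeric vector `c(gm=, wm=, csf=)` applied
#'   to every component, or a matrix with one row per `physio_freqs` entry
#'   and columns `gm`, `wm`, `csf` (e.g. respiratory weights vs much
#'   stronger cardiac pulsatility near vessels).
#' @param physio_amp_cv SD of the subject-level fluctuation of physiological
#'   component amplitudes around 1.
#' @param physio_session_cv SD of the session-level multiplicative jitter of
#'   physiological amplitudes (breathing depth and heart rate vary between
#'   runs).
#' @param motion_coupling weight of the realignment-parameter-derived signal.
#' @param thermal_noise_sd white-noise SD (a.u.).
#' @param bias_field_range `c(min, max)` multiplicative gain of the smooth
#'   bias field; both strictly positive.
#' @param session_drift_jitter session-level SD of drift-coefficient jitter,
#'   expressed as a fraction of `drift_coeff_sd`.
#' @param baseline constant tissue baseline (a.u.); identical across
#'   compartments because the DC bin is excluded from all spectral measures.
#' @param rng_seed integer seed; the whole group is a deterministic function
#'   of the configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_subject()], [generate_group()]
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 2, n_sessions = 1,
#'                          n_timepoints = 32, grid_dims = c(8, 8, 8))
#' cfg$lff_band
simulation_config <- function(n_subjects = 20,
                              n_sessions = 2,
                              n_timepoints = 128,
                              tr_seconds = 2,
                              grid_dims = c(16L, 16L, 10L),
                              voxel_size_mm = c(3, 3, 3),
                              lff_band = c(0.01, 0.1),
                              gm_lff_sd = 1,
                              gm_lff_exponent = 2,
                              drift_coeff_sd = c(1, 0.5, 0.2),
                              slow_drift_sd = 0.3,
                              slow_drift_band = c(0.004, 0.04),
                              n_slow_components = 16L,
                              drift_severity_cv = 0.6,
                              drift_profile_range = c(0.25, 1.75),
                              drift_tissue_weight = c(gm = 1, wm = 1.5, csf = 5),
                              physio_freqs = c(0.07, 0.19),
                              physio_bandwidth_hz = 0.02,
                              physio_coupling = rbind(
                                resp    = c(gm = 1.2, wm = 1, csf = 2),
                                cardiac = c(gm = 2.5, wm = 1, csf = 3)),
                              physio_amp_cv = 0.5,
                              physio_session_cv = 0.3,
                              motion_coupling = 2.5,
                              thermal_noise_sd = 2.5,
                              bias_field_range = c(0.8, 1.2),
                              session_drift_jitter = 0.1,
                              baseline = 100,
                              rng_seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = as.numeric(tr_seconds),
    grid_dims = as.integer(grid_dims),
    voxel_size_mm = as.numeric(voxel_size_mm),
    lff_band = as.numeric(lff_band),
    gm_lff_sd = as.numeric(gm_lff_sd),
    gm_lff_exponent = as.numeric(gm_lff_exponent),
    drift_coeff_sd = rep(as.numeric(drift_coeff_sd), length.out = 3L),
    slow_drift_sd = as.numeric(slow_drift_sd),
    slow_drift_band = as.numeric(slow_drift_band),
    n_slow_components = as.integer(n_slow_components),
    drift_severity_cv = as.numeric(drift_severity_cv),
    drift_profile_range = as.numeric(drift_profile_range),
    drift_tissue_weight = drift_tissue_weight,
    physio_freqs = as.numeric(physio_freqs),
    physio_bandwidth_hz = as.numeric(physio_bandwidth_hz),
    physio_coupling = physio_coupling,
    physio_amp_cv = as.numeric(physio_amp_cv),
    physio_session_cv = as.numeric(physio_session_cv),
    motion_coupling = as.numeric(motion_coupling),
    thermal_noise_sd = as.numeric(thermal_noise_sd),
    bias_field_range = as.numeric(bias_field_range),
    session_drift_jitter = as.numeric(session_drift_jitter),
    baseline = as.numeric(baseline),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants of [simulation_config()] and stops with an
#' informative message on the first violation.
#'
#' @param cfg a `sim_config` object.
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (cfg$n_sessions < 1L) stop("n_sessions must be >= 1")
  if (cfg$n_timepoints < 16L) stop("n_timepoints must be >= 16")
  if (!is.finite(cfg$tr_seconds) || cfg$tr_seconds <= 0)
    stop("tr_seconds must be positive")
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 8L))
    stop("grid_dims must be three voxel counts, each >= 8, so that the ",
         "grid can host three disjoint tissue compartments")
  if (length(cfg$voxel_size_mm) != 3L || any(cfg$voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive lengths")
  nyq <- 1 / (2 * cfg$tr_seconds)
  if (length(cfg$lff_band) != 2L || cfg$lff_band[1] <= 0 ||
      cfg$lff_band[1] >= cfg$lff_band[2])
    stop("lff_band must be c(low, high) with 0 < low < high")
  if (cfg$lff_band[2] >= nyq)
    stop(sprintf("lff_band upper edge (%g Hz) must be below Nyquist (%g Hz)",
                 cfg$lff_band[2], nyq))
  sds <- c(cfg$gm_lff_sd, cfg$drift_coeff_sd, cfg$slow_drift_sd,
           cfg$thermal_noise_sd, cfg$physio_amp_cv, cfg$physio_session_cv,
           cfg$drift_severity_cv, cfg$session_drift_jitter)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all SD/CV parameters must be finite and >= 0")
  if (any(cfg$physio_freqs <= 0) || any(cfg$physio_freqs > nyq))
    stop("physio_freqs must lie in (0, Nyquist]")
  if (!is.finite(cfg$physio_bandwidth_hz) || cfg$physio_bandwidth_hz < 0)
    stop("physio_bandwidth_hz must be finite and >= 0")
  if (cfg$n_slow_components < 1L) stop("n_slow_components must be >= 1")
  if (length(cfg$slow_drift_band) != 2L || cfg$slow_drift_band[1] <= 0 ||
      cfg$slow_drift_band[1] >= cfg$slow_drift_band[2] ||
      cfg$slow_drift_band[2] > nyq)
    stop("slow_drift_band must satisfy 0 < low < high <= Nyquist")
  if (length(cfg$drift_profile_range) != 2L ||
      any(cfg$drift_profile_range <= 0) ||
      cfg$drift_profile_range[1] > cfg$drift_profile_range[2])
    stop("drift_profile_range must be 0 < min <= max")
  if (!all(c("gm", "wm", "csf") %in% names(cfg$drift_tissue_weight)) ||
      any(cfg$drift_tissue_weight < 0))
    stop("drift_tissue_weight needs nonnegative gm, wm and csf entries")
  if (length(cfg$bias_field_range) != 2L ||
      any(cfg$bias_field_range <= 0) ||
      cfg$bias_field_range[1] > cfg$bias_field_range[2])
    stop("bias_field_range must be 0 < min <= max")
  pc <- cfg$physio_coupling
  pc_names <- if (is.matrix(pc)) colnames(pc) else names(pc)
  if (!all(c("gm", "wm", "csf") %in% pc_names))
    stop("physio_coupling must have gm, wm and csf entries")
  if (is.matrix(pc) && nrow(pc) != length(cfg$physio_freqs))
    stop("physio_coupling matrix needs one row per physio frequency")
  invisible(cfg)
}

#' Read a simulation configuration from JSON or YAML
#'
#' The document must be a mapping whose keys mirror the arguments of
#' [simulation_config()]; missing keys fall back to the defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be a .json, .yaml or .yml document: ", path)
  }
  if (!is.null(fields$physio_coupling))
    fields$physio_coupling <- unlist(fields$physio_coupling)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0)
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  do.call(simulation_config, fields)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d subjects x %d sessions, N = %d, TR = %g s, grid %s\n",
    x$n_subjects, x$n_sessions, x$n_timepoints, x$tr_seconds,
    paste(x$grid_dims, collapse = "x")))
  cat(sprintf("  band %g-%g Hz, gm_lff_sd %g, drift_coeff_sd %g, slow_drift_sd %g\n",
              x$lff_band[1], x$lff_band[2], x$gm_lff_sd, x$drift_coeff_sd,
              x$slow_drift_sd))
  cat(sprintf("  thermal_noise_sd %g, motion_coupling %g, seed %d\n",
              x$thermal_noise_sd, x$motion_coupling, x$rng_seed))
  invisible(x)
}
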