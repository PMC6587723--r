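# Enumeration and execution of the 16 nuisance-regression pipelines.

.BLOCK_NAMES <- c("detr", "wm", "csf", "rp")

#' Construct a pipeline specification
#'
#' One combination of the four nuisance regressor blocks, plus processing
#' options.
#'
#' @param use_detr,use_wm,use_csf,use_rp logical flags for the four blocks.
#' @param detrend_mode `"polynomial"` (constant/linear/quadratic trends) or
#'   `"exploratory"` (lag-one CCA trends from non-GM voxels); only relevant
#'   when `use_detr` is `TRUE`.
#' @param surrogate replace all regressors by phase-randomised surrogates
#'   (requires at least one active block).
#' @param bias_correct divide the data by the (known) bias field first.
#' @param measures subset of `c("alff", "falff", "hfalff")`.
#' @return An object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(use_detr = FALSE, use_wm = FALSE,
                          use_csf = FALSE, use_rp = FALSE,
                          detrend_mode = c("polynomial", "exploratory"),
                          surrogate = FALSE, bias_correct = FALSE,
                          measures = c("alff", "falff", "hfalff")) {
  detrend_mode <- match.arg(detrend_mode)
  measures <- match.arg(measures, c("alff", "falff", "hfalff"),
                        several.ok = TRUE)
  if (surrogate && !any(use_detr, use_wm, use_csf, use_rp))
    stop("surrogate regression requires at least one active block")
  structure(list(use_detr = isTRUE(use_detr), use_wm = isTRUE(use_wm),
                 use_csf = isTRUE(use_csf), use_rp = isTRUE(use_rp),
                 detrend_mode = detrend_mode, surrogate = isTRUE(surrogate),
                 bias_correct = isTRUE(bias_correct), measures = measures),
            class = "pipeline_spec")
}

#' Label of a pipeline specification
#'
#' Active blocks joined by `+` in the stable order detr, wm, csf, rp;
#' the empty combination is `"none"`.  `parse_pipeline_label()` inverts it.
#'
#' @param spec a [pipeline_spec()].
#' @return Character label, e.g. `"detr+wm+csf+rp"`.
#' @export
pipeline_label <- function(spec) {
  on <- .BLOCK_NAMES[c(spec$use_detr, spec$use_wm, spec$use_csf, spec$use_rp)]
  if (length(on) == 0L) "none" else paste(on, collapse = "+")
}

#' @rdname pipeline_label
#' @param label a label produced by [pipeline_label()].
#' @param ... further arguments passed to [pipeline_spec()].
#' @export
parse_pipeline_label <- function(label, ...) {
  if (identical(label, "none")) return(pipeline_spec(...))
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  if (!all(parts %in% .BLOCK_NAMES) || anyDuplicated(parts))
    stop("not a valid pipeline label: ", label)
  pipeline_spec(use_detr = "detr" %in% parts, use_wm = "wm" %in% parts,
                use_csf = "csf" %in% parts, use_rp = "rp" %in% parts, ...)
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf("<pipeline_spec> %s%s%s (%s detrending), measures: %s\n",
              pipeline_label(x),
              if (x$surrogate) " [surrogate]" else "",
              if (x$bias_correct) " [bias-corrected]" else "",
              x$detrend_mode, paste(x$measures, collapse = ", ")))
  invisible(x)
}

#' Enumerate the 16 nuisance-regression pipelines
#'
#' All `2^4` on/off combinations of the detrending, WM, CSF and RP blocks,
#' in stable binary-counting order (`none`, `detr`, `wm`, `detr+wm`, ...),
#' deterministically labelled.
#'
#' @param ... options (e.g. `detrend_mode`, `measures`) applied to every
#'   spec; `surrogate` is not allowed here because the empty combination
#'   cannot be randomised.
#' @return Named list of 16 `pipeline_spec`s.
#' @export
enumerate_pipelines <- function(...) {
  grid <- expand.grid(detr = c(FALSE, TRUE), wm = c(FALSE, TRUE),
                      csf = c(FALSE, TRUE), rp = c(FALSE, TRUE))
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    pipeline_spec(use_detr = grid$detr[i], use_wm = grid$wm[i],
                  use_csf = grid$csf[i], use_rp = grid$rp[i], ...)
  })
  names(specs) <- vapply(specs, pipeline_label, "")
  specs
}

#' Build the nuisance regressor blocks of one data set
#'
#' Extracts and orthogonalises all four blocks once, so that several
#' pipelines can reuse them.  WM and CSF blocks are six regressors each
#' (mean + five principal components) from thresholded, optionally eroded
#' tissue maps; all non-detrending blocks are orthogonalised against the
#' polynomial trends; exploratory trends are estimated from the pooled
#' non-GM voxels and never orthogonalised.
#'
#' @param dataset a `subject_dataset` (or a list with fields `bold`,
#'   `masks`, `realignment_params`, `tr_seconds`).
#' @param detrend_mode `"polynomial"` or `"exploratory"`.
#' @param tissue_threshold probability threshold for the WM/CSF masks; the
#'   generator's masks are binary, so the synthetic default is 0.5.
#' @param erosion_voxels erosion passes for the tissue masks (default 0 on
#'   the small synthetic grid; use 1 with real probability maps).
#' @param bold optional 4D array overriding `dataset$bold` (e.g. after bias
#'   correction).
#' @return Named list of orthogonalised `regressor_block`s
#'   (`detr`, `wm`, `csf`, `rp`).
#' @export
prepare_blocks <- function(dataset, detrend_mode = "polynomial",
                           tissue_threshold = 0.5, erosion_voxels = 0L,
                           bold = NULL) {
  if (is.null(bold)) bold <- dataset$bold
  n <- dim(bold)[4]
  poly <- polynomial_block(n)

  wm_ex <- extract_tissue_timecourses(bold, dataset$masks$wm + 0,
                                      tissue_threshold, erosion_voxels)
  csf_ex <- extract_tissue_timecourses(bold, dataset$masks$csf + 0,
                                       tissue_threshold, erosion_voxels)
  blocks <- list(
    wm = pca_block(wm_ex$timecourses, 5L, "WM"),
    csf = pca_block(csf_ex$timecourses, 5L, "CSF"),
    rp = rp_block(dataset$realignment_params)
  )
  blocks <- orthogonalise(blocks, reference = poly)
  names(blocks) <- tolower(vapply(blocks, `[[`, "", "name"))
  if (!all(c("wm", "csf", "rp") %in% names(blocks)))
    stop("a tissue or RP block was lost during orthogonalisation")

  detr <- if (identical(detrend_mode, "polynomial")) {
    poly
  } else {
    non_gm <- cbind(wm_ex$timecourses, csf_ex$timecourses)
    exploratory_trends(non_gm)
  }
  c(list(detr = detr), blocks)
}

# all-measures map computation from an N x V residual matrix
.maps_from_tc <- function(tc, tr, band, measures, mask) {
  n <- nrow(tc)
  proto <- compute_spectrum(tc[, 1L], tr)
  nyq <- 1 / (2 * tr)
  mags <- Mod(mvfft(tc))[seq_len(n %/% 2 + 1L), , drop = FALSE]
  num <- colSums(mags[.spec_bins(proto, band[1], band[2]), , drop = FALSE])
  dims <- dim(mask)
  out <- list()
  for (measure in measures) {
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
    values <- array(0, dim = dims)
    values[which(mask)] <- vals
    out[[measure]] <- fluctuation_map(values, measure, band, mask)
  }
  out
}

#' Run one pipeline on one data set
#'
#' Builds (or reuses) the regressor blocks, assembles the design from the
#' active blocks, removes it by least squares, and computes one standardised
#' (and optionally smoothed) fluctuation map per requested measure.  With
#' `spec$surrogate` the regression is repeated with `n_surrogate`
#' phase-randomised copies of the assembled regressors and each measure
#' yields a list of per-repetition maps.
#'
#' @param dataset a `subject_dataset`.
#' @param spec a [pipeline_spec()].
#' @param band analysis band in Hz; defaults to the data set's band.
#' @param fwhm_mm Gaussian smoothing FWHM in mm (0 to disable).
#' @param voxel_size_mm voxel size for smoothing.
#' @param blocks optional precomputed [prepare_blocks()] result.
#' @param n_surrogate surrogate repetitions (default 25).
#' @param tissue_threshold,erosion_voxels passed to [prepare_blocks()].
#' @return A list of class `pipeline_result`: `maps` (per measure, a
#'   `fluctuation_map`, or a list of them when `spec$surrogate`), `spec`,
#'   `label`, `n_regressors`.
#' @export
apply_pipeline <- function(dataset, spec, band = NULL, fwhm_mm = 6,
                           voxel_size_mm = c(3, 3, 3), blocks = NULL,
                           n_surrogate = 25L, tissue_threshold = 0.5,
                           erosion_voxels = 0L) {
  stopifnot(inherits(spec, "pipeline_spec"))
  if (is.null(band)) band <- dataset$lff_band
  if (is.null(band)) band <- c(0.01, 0.1)
  bold <- dataset$bold
  if (spec$bias_correct)
    bold <- apply_bias_correction(bold, dataset$bias_field)
  if (is.null(blocks))
    blocks <- prepare_blocks(dataset, detrend_mode = spec$detrend_mode,
                             tissue_threshold = tissue_threshold,
                             erosion_voxels = erosion_voxels, bold = bold)
  if (spec$use_rp && is.null(dataset$realignment_params))
    stop("pipeline requests the RP block but the data set has no ",
         "realignment parameters")

  brain <- dataset$masks$gm | dataset$masks$wm | dataset$masks$csf
  tc <- .mask_timecourses(bold, brain)
  tr <- dataset$tr_seconds

  maps <- .execute_pipeline(tc, blocks, spec, tr, band, brain,
                            fwhm_mm, voxel_size_mm, n_surrogate)
  active <- blocks[c(spec$use_detr, spec$use_wm, spec$use_csf, spec$use_rp)]
  structure(list(maps = maps, spec = spec, label = pipeline_label(spec),
                 n_regressors = sum(vapply(active, function(b)
                   ncol(b$columns), 0L))),
            class = "pipeline_result")
}

# Shared execution core: residualise the in-mask time courses against the
# active blocks of `spec`, then compute standardised, smoothed maps.
# Returns one fluctuation_map per measure, or (surrogate) a list of
# per-repetition maps per measure.
.execute_pipeline <- function(tc, blocks, spec, tr, band, brain_mask,
                              fwhm_mm, voxel_size_mm, n_surrogate = 25L) {
  active <- blocks[c(spec$use_detr, spec$use_wm, spec$use_csf, spec$use_rp)]
  finish <- function(res_tc) {
    maps <- .maps_from_tc(res_tc, tr, band, spec$measures, brain_mask)
    lapply(maps, function(m) {
      m <- standardise_map(m, brain_mask)
      if (fwhm_mm > 0) m <- gaussian_smooth(m, fwhm_mm, voxel_size_mm)
      m
    })
  }
  if (length(active) == 0L) {
    finish(tc)
  } else if (!spec$surrogate) {
    finish(regress_out(tc, design_matrix(unname(active))))
  } else {
    sets <- phase_randomise(unname(active), n_repetitions = n_surrogate)
    per_rep <- lapply(sets, function(s)
      finish(regress_out(tc, design_matrix(s))))
    maps <- lapply(spec$measures, function(m) lapply(per_rep, `[[`, m))
    names(maps) <- spec$measures
    maps
  }
}
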