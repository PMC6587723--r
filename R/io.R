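# NIfTI-1, TSV and JSON-sidecar I/O.

.write_nifti <- function(arr, path, pixdims) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write realignment parameters as TSV
#'
#' Six columns with the header `trans_x, trans_y, trans_z, rot_x, rot_y,
#' rot_z` (translations in mm, rotations in rad).
#'
#' @param rp N x 6 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_realignment_tsv <- function(rp, path) {
  rp <- as.matrix(rp)
  if (ncol(rp) != 6L) stop("realignment parameters must have 6 columns")
  colnames(rp) <- c("trans_x", "trans_y", "trans_z",
                    "rot_x", "rot_y", "rot_z")
  write.table(rp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read realignment parameters from TSV
#'
#' @param path TSV with the header written by [write_realignment_tsv()].
#' @return N x 6 numeric matrix.
#' @export
read_realignment_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!identical(colnames(df), need))
    stop("expected columns ", paste(need, collapse = ", "))
  as.matrix(df)
}

#' Write a synthetic data set as NIfTI + TSV + JSON
#'
#' Writes `bold.nii`, the three tissue masks, the bias field, the
#' realignment TSV, and the ground truth as a JSON + TSV sidecar bundle.
#'
#' @param dataset a `subject_dataset`.
#' @param dir output directory (created if needed).
#' @param voxel_size_mm voxel size recorded in the NIfTI headers.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, voxel_size_mm = c(3, 3, 3)) {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- as.numeric(voxel_size_mm)
  .write_nifti(dataset$bold, file.path(dir, "bold.nii"),
               c(vox, dataset$tr_seconds))
  for (tis in names(dataset$masks))
    .write_nifti(dataset$masks[[tis]] + 0,
                 file.path(dir, paste0("mask_", tis, ".nii")), vox)
  .write_nifti(dataset$bias_field, file.path(dir, "bias_field.nii"), vox)
  write_realignment_tsv(dataset$realignment_params,
                        file.path(dir, "realignment.tsv"))

  gt <- dataset$ground_truth
  .write_nifti(gt$amplitude_map, file.path(dir, "true_amplitude.nii"), vox)
  tcs <- cbind(drift = gt$drift, gt$physio)
  colnames(tcs) <- c("drift", sprintf("physio_%d", seq_len(ncol(gt$physio))))
  write.table(tcs, file.path(dir, "ground_truth_timecourses.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    subject_index = dataset$subject_index,
    session_index = dataset$session_index,
    tr_seconds = dataset$tr_seconds,
    lff_band = dataset$lff_band,
    drift_coeffs_subject = gt$drift_coeffs_subject,
    drift_coeffs_session = gt$drift_coeffs_session,
    physio_amps = gt$physio_amps,
    slow_amp = gt$slow_amp
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a data set written by [write_dataset()]
#'
#' @param dir the dataset directory.
#' @return A `subject_dataset` (ground-truth time courses and JSON fields
#'   restored; the bias field and masks re-read from NIfTI).
#' @export
read_dataset <- function(dir) {
  bold_img <- RNifti::readNifti(file.path(dir, "bold.nii"))
  bold <- array(as.numeric(bold_img), dim = dim(bold_img))
  masks <- lapply(c(gm = "gm", wm = "wm", csf = "csf"), function(tis) {
    arr <- RNifti::readNifti(file.path(dir, paste0("mask_", tis, ".nii")))
    array(as.numeric(arr) > 0.5, dim = dim(arr))
  })
  bias <- RNifti::readNifti(file.path(dir, "bias_field.nii"))
  meta <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  tcs <- read.table(file.path(dir, "ground_truth_timecourses.tsv"),
                    header = TRUE, sep = "\t")
  amp <- RNifti::readNifti(file.path(dir, "true_amplitude.nii"))
  structure(list(
    bold = bold,
    masks = masks,
    realignment_params = read_realignment_tsv(
      file.path(dir, "realignment.tsv")),
    bias_field = array(as.numeric(bias), dim = dim(bias)),
    ground_truth = list(
      drift = tcs$drift,
      drift_coeffs_subject = meta$drift_coeffs_subject,
      drift_coeffs_session = meta$drift_coeffs_session,
      physio = as.matrix(tcs[, -1, drop = FALSE]),
      physio_amps = meta$physio_amps,
      amplitude_map = array(as.numeric(amp), dim = dim(amp)),
      slow_amp = meta$slow_amp,
      motion_signal = NULL),
    tr_seconds = meta$tr_seconds,
    lff_band = meta$lff_band,
    subject_index = meta$subject_index,
    session_index = meta$session_index
  ), class = "subject_dataset")
}

#' Write a fluctuation map as NIfTI with a JSON sidecar
#'
#' @param map a [fluctuation_map()].
#' @param path output `.nii` path; the sidecar replaces the extension with
#'   `.json`.
#' @param voxel_size_mm voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
write_fluctuation_map <- function(map, path, voxel_size_mm = c(3, 3, 3)) {
  stopifnot(inherits(map, "fluctuation_map"))
  vals <- map$values
  vals[is.na(vals)] <- 0
  .write_nifti(vals, path, as.numeric(voxel_size_mm))
  jsonlite::write_json(list(
    measure = map$measure, band = map$band,
    standardised = map$standardised,
    smoothing_fwhm_mm = map$smoothing_fwhm_mm
  ), sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fluctuation map written by [write_fluctuation_map()]
#'
#' @param path the `.nii` path.
#' @param mask optional logical 3D array; defaults to nonzero voxels.
#' @return A [fluctuation_map()].
#' @export
read_fluctuation_map <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim = dim(img))
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  if (is.null(mask)) mask <- values != 0
  fluctuation_map(values, meta$measure, meta$band, mask,
                  standardised = isTRUE(meta$standardised),
                  smoothing_fwhm_mm = meta$smoothing_fwhm_mm)
}

#' Write a statistic map as NIfTI with a JSON sidecar
#'
#' @param map a [stat_map()].
#' @param path output `.nii` path.
#' @param voxel_size_mm voxel size recorded in the header.
#' @param pipeline optional pipeline label recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path, voxel_size_mm = c(3, 3, 3),
                           pipeline = NULL) {
  stopifnot(inherits(map, "stat_map"))
  vals <- map$values
  vals[is.na(vals)] <- 0
  .write_nifti(vals, path, as.numeric(voxel_size_mm))
  jsonlite::write_json(list(
    statistic = map$statistic, n_subjects = map$n_subjects,
    pipeline = pipeline
  ), sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write regressor blocks as TSV
#'
#' One column per regressor, named `<block>_<index>`.
#'
#' @param blocks a `regressor_block` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  if (inherits(blocks, "regressor_block")) blocks <- list(blocks)
  x <- do.call(cbind, lapply(blocks, `[[`, "columns"))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
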