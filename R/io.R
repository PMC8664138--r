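# Disk format for image pairs: two float32 NIfTI volumes (low.nii.gz,
# high.nii.gz) plus a JSON sidecar (pair.json) carrying the acquisition
# metadata. Externally supplied pairs in the same layout can be read back
# into the pipeline.

#' Write an image pair to a directory
#'
#' Writes `low.nii.gz` and `high.nii.gz` (float32 HU) and a `pair.json`
#' sidecar with the acquisition metadata. Round-trips through
#' [read_pair()] are lossless at 32-bit float precision.
#'
#' @param pair A `dect_pair`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_pair <- function(pair, dir) {
  if (!inherits(pair, "dect_pair")) stop_validation("`pair` must be a dect_pair")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- pair$meta
  pd <- c(m$pixel_spacing_mm, m$pixel_spacing_mm, m$slice_thickness_mm)
  RNifti::writeNifti(RNifti::asNifti(pair$low, datatype = "float"),
                     file.path(dir, "low.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(pair$high, datatype = "float"),
                     file.path(dir, "high.nii.gz"))
  acq <- m$acquisition
  sidecar <- list(
    modality = acq$modality$name,
    low_label = acq$modality$low_label,
    high_label = acq$modality$high_label,
    mixed_weight = acq$modality$mixed_weight,
    size_label = m$size,
    ctdivol_mGy = acq$ctdivol_mGy,
    mas_fraction = acq$mas_fraction,
    admire_strength = acq$admire_strength,
    seed = acq$seed,
    spacing_mm = pd,
    noisy = isTRUE(m$noisy),
    shape = dim(pair$low)
  )
  jsonlite::write_json(sidecar, file.path(dir, "pair.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an image pair from a directory
#'
#' @param dir Directory containing `low.nii.gz`, `high.nii.gz` and
#'   `pair.json` as written by [write_pair()].
#' @return A `dect_pair`.
#' @export
read_pair <- function(dir) {
  sidecar_path <- file.path(dir, "pair.json")
  if (!file.exists(sidecar_path)) {
    stop_format(sprintf("missing sidecar file '%s'", sidecar_path))
  }
  for (f in c("low.nii.gz", "high.nii.gz")) {
    if (!file.exists(file.path(dir, f))) {
      stop_format(sprintf("missing volume file '%s'", file.path(dir, f)))
    }
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  low <- RNifti::readNifti(file.path(dir, "low.nii.gz"))
  high <- RNifti::readNifti(file.path(dir, "high.nii.gz"))
  low <- array(as.numeric(low), dim = dim(low))
  high <- array(as.numeric(high), dim = dim(high))
  if (!identical(dim(low), dim(high))) {
    stop_format("low and high volumes have different shapes")
  }
  if (!is.null(sidecar$shape) &&
      !identical(as.integer(dim(low)), as.integer(sidecar$shape))) {
    stop_format("volume shape does not match the sidecar metadata")
  }

  modality <- dect_modality(sidecar$modality,
                            mixed_weight = sidecar$mixed_weight)
  acq <- acquisition_spec(
    modality = modality, size = sidecar$size_label,
    ctdivol_mGy = sidecar$ctdivol_mGy, mas_fraction = sidecar$mas_fraction,
    admire_strength = sidecar$admire_strength, seed = sidecar$seed
  )
  meta <- list(
    acquisition = acq, size = sidecar$size_label, modality = modality,
    pixel_spacing_mm = sidecar$spacing_mm[1],
    slice_thickness_mm = sidecar$spacing_mm[3],
    inserts = NULL, noisy = isTRUE(sidecar$noisy),
    admire_applied = sidecar$admire_strength
  )
  new_dect_pair(low, high, meta)
}
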