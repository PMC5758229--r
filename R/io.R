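#' Write an image volume as NIfTI
#'
#' Stores the array with its voxel spacing in the NIfTI header
#' (gzip-compressed if the path ends in `.nii.gz`).
#'
#' @param vol an `image_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  data <- vol$data
  if (is.logical(data)) storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an image volume from NIfTI
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param modality modality tag to attach (`"SUV"`, `"HU"` or `"mask"`).
#' @return an `image_volume`.
#' @export
read_volume_nifti <- function(path, modality = "SUV") {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  data <- array(as.numeric(img), dim(img))
  if (modality == "mask") data <- array(data > 0, dim(img))
  image_volume(data, spacing, modality)
}

#' Write a phantom case to disk
#'
#' PET, CT and ground-truth mask as NIfTI plus a JSON sidecar with the
#' lesion specification, seed and true volume.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @param stem file stem; defaults to the `case_id` or `"case"`.
#' @return the sidecar path, invisibly.
#' @export
write_phantom_case <- function(case, dir, stem = NULL) {
  stopifnot(inherits(case, "phantom_case"))
  if (is.null(stem)) stem <- if (!is.null(case$case_id)) case$case_id else "case"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume_nifti(case$pet, file.path(dir, paste0(stem, "_pet.nii.gz")))
  write_volume_nifti(case$ct, file.path(dir, paste0(stem, "_ct.nii.gz")))
  mask_vol <- image_volume(case$truth_mask, case$ct$spacing_mm, "mask")
  write_volume_nifti(mask_vol, file.path(dir, paste0(stem, "_truth.nii.gz")))
  meta <- c(case$spec[!vapply(case$spec, is.null, TRUE)],
            list(truth_volume_mm3 = case$truth_volume_mm3,
                 suv_max = case$suv_max, seed = case$seed))
  side <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
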