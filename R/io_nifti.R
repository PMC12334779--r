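#' Read a CT volume from NIfTI or a DICOM series
#'
#' Loads a HU-calibrated volume and canonicalizes it to the package's
#' anatomical storage order (cranial-caudal, ventral-dorsal, left-right) using
#' the header orientation. Dual-energy virtual non-contrast reconstructions are
#' treated as ordinary HU volumes. Files without orientation metadata are
#' rejected rather than guessed at.
#'
#' @param path Path to a `.nii`/`.nii.gz` file, or a directory containing one
#'   DICOM series.
#' @param format `"nifti"` or `"dicom_series"`; the default guesses from
#'   `path` (directory implies DICOM).
#' @param source_id Scan identifier; defaults to the file/directory name.
#' @return A [ct_volume()].
#' @seealso [write_ct()], [read_lung_mask()]
#' @export
read_ct <- function(path, format = c("auto", "nifti", "dicom_series"),
                    source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Input '%s' does not exist.", path),
      class = "focalindex_read_error"
    )
  }
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  source_id <- source_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  if (format == "dicom_series") {
    return(read_dicom_series(path, source_id = source_id))
  }
  img <- tryCatch(RNifti::readNifti(path),
    error = function(e) {
      abort(sprintf("Failed to read NIfTI '%s': %s", path, conditionMessage(e)),
        class = "focalindex_read_error"
      )
    }
  )
  if (length(dim(img)) != 3L) {
    abort("Only 3-D volumes are supported.", class = "focalindex_read_error")
  }
  xf <- RNifti::xform(img)
  if (identical(attr(xf, "code"), 0L)) {
    abort(
      paste(
        "NIfTI header carries no orientation (qform and sform codes are 0);",
        "refusing to guess anatomical axes."
      ),
      class = "focalindex_orientation_error"
    )
  }
  RNifti::orientation(img) <- "IPR"
  ct_volume(as.array(img), spacing = RNifti::pixdim(img), source_id = source_id)
}

# Affine mapping canonical voxel indices to RAS+ world coordinates:
# axis 1 points Inferior, axis 2 Posterior, axis 3 Right.
.canonical_affine <- function(spacing) {
  aff <- matrix(0, 4, 4)
  aff[3, 1] <- -spacing[1]
  aff[2, 2] <- -spacing[2]
  aff[1, 3] <- spacing[3]
  aff[4, 4] <- 1
  aff
}

.as_nifti <- function(arr, spacing, datatype = "double") {
  img <- RNifti::asNifti(structure(arr, pixdim = spacing), datatype = datatype)
  RNifti::qform(img) <- structure(.canonical_affine(spacing), code = 2L)
  RNifti::sform(img) <- structure(.canonical_affine(spacing), code = 2L)
  img
}

#' Write a CT volume or lung mask to NIfTI
#'
#' Volumes are written in canonical orientation with a full affine, so a
#' write/read round trip preserves voxels, spacing and orientation exactly.
#'
#' @param volume A [ct_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  RNifti::writeNifti(.as_nifti(volume$voxels, volume$spacing), path, datatype = "double")
  invisible(path)
}

#' @rdname write_ct
#' @param mask A [lung_mask()].
#' @param spacing Voxel spacing in mm for the mask header.
#' @export
write_lung_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(mask, "lung_mask"))
  arr <- array(as.integer(mask), dim = dim(mask))
  RNifti::writeNifti(.as_nifti(arr, spacing, datatype = "uint8"), path)
  invisible(path)
}

#' Read a binary lung mask from NIfTI
#'
#' The mask is canonicalized with the same header-based reorientation as
#' [read_ct()]; values must be 0/1.
#'
#' @inheritParams read_ct
#' @return A [lung_mask()].
#' @export
read_lung_mask <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Mask '%s' does not exist.", path),
      class = "focalindex_read_error"
    )
  }
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  if (identical(attr(xf, "code"), 0L)) {
    abort("Mask NIfTI carries no orientation metadata.",
      class = "focalindex_orientation_error"
    )
  }
  RNifti::orientation(img) <- "IPR"
  arr <- as.array(img)
  if (!all(arr %in% c(0, 1))) {
    abort("Mask values must be 0 or 1.", class = "focalindex_read_error")
  }
  lung_mask(arr == 1)
}
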