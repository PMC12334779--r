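#' Semiautomatic lung parenchyma segmentation
#'
#' Fallback segmentation for scans without an externally supplied mask, using
#' the standard quantitative-CT recipe: threshold the volume at an aerated-lung
#' HU cutoff, discard the exterior-air component (anything touching the
#' in-plane image border), keep sufficiently large 3-D connected components,
#' and apply a morphological closing so dense consolidations enclosed by
#' aerated lung are re-included. Optional seed points provide the
#' "semiautomatic" interaction: when given, only components containing a seed
#' are kept. An externally supplied mask always takes precedence over this
#' routine in the pipeline.
#'
#' @param volume A canonical [ct_volume()].
#' @param air_threshold HU cutoff; voxels strictly below it are lung
#'   candidates. Must lie in (-1000, 0). Default -300.
#' @param min_component_volume_ml Minimum connected-component volume retained,
#'   in ml. Default 50.
#' @param closing_radius_mm Radius of the closing ball, mm. Default 3.
#' @param seed_points Optional integer matrix (rows = voxels, columns =
#'   canonical axes 1..3); only components containing a seed are kept.
#' @return A [lung_mask()].
#' @export
segment_lungs <- function(volume, air_threshold = -300,
                          min_component_volume_ml = 50,
                          closing_radius_mm = 3, seed_points = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!(air_threshold > -1000 && air_threshold < 0)) {
    abort("`air_threshold` must lie in (-1000, 0) HU.",
      class = "focalindex_input_error"
    )
  }
  if (closing_radius_mm < 0 || min_component_volume_ml <= 0) {
    abort("`closing_radius_mm` must be >= 0 and `min_component_volume_ml` > 0.",
      class = "focalindex_input_error"
    )
  }
  candidate <- volume$voxels < air_threshold
  if (!any(candidate)) {
    abort(
      paste(
        "Segmentation failed: no voxels below the air threshold.",
        "Check the HU calibration or raise `air_threshold`."
      ),
      class = "focalindex_segmentation_error"
    )
  }
  comp <- .label_components(candidate)
  dims <- dim(candidate)
  # exterior air: any component touching the in-plane (axial image) border
  border <- array(FALSE, dims)
  border[, c(1, dims[2]), ] <- TRUE
  border[, , c(1, dims[3])] <- TRUE
  border_labels <- setdiff(unique(comp$labels[border & candidate]), 0L)
  voxel_ml <- prod(volume$spacing) / 1000
  keep <- setdiff(which(comp$sizes * voxel_ml >= min_component_volume_ml), border_labels)
  if (!is.null(seed_points)) {
    seed_points <- matrix(as.integer(seed_points), ncol = 3)
    seed_labels <- comp$labels[seed_points]
    keep <- intersect(keep, seed_labels)
  }
  if (!length(keep)) {
    abort(
      paste(
        "Segmentation failed: every candidate component touches the image",
        "border, is smaller than `min_component_volume_ml`, or contains no seed.",
        "The field of view may crop the lungs or the threshold may be too low."
      ),
      class = "focalindex_segmentation_error"
    )
  }
  mask <- array(comp$labels %in% keep, dims)
  lung_mask(.close3(mask, closing_radius_mm, volume$spacing))
}
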