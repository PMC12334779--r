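#' CT volume container
#'
#' A `ct_volume` holds a 3-D array of Hounsfield units in the package's
#' canonical anatomical order together with its physical voxel spacing.
#' Canonical storage order is: axis 1 cranial to caudal, axis 2 ventral to
#' dorsal (the gravitational axis in a supine patient), axis 3 left to right.
#'
#' @param voxels Numeric 3-D array of HU values.
#' @param spacing Numeric length-3 vector, mm per voxel along each axis
#'   (cranial-caudal, ventral-dorsal, left-right). All strictly positive.
#' @param source_id Opaque scan identifier (character).
#'
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `axes` and `source_id`.
#' @export
#' @examples
#' v <- ct_volume(array(-500, c(4, 4, 4)), spacing = c(1.5, 1, 1))
#' dim(v$voxels)
ct_volume <- function(voxels, spacing = c(1, 1, 1), source_id = "unknown") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3-D array.", class = "focalindex_input_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive numbers (mm).",
      class = "focalindex_input_error"
    )
  }
  structure(
    list(
      voxels = array(as.numeric(voxels), dim(voxels)), # plain double array
      spacing = spacing,
      axes = .CANONICAL_AXES,
      source_id = as.character(source_id)[1]
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume '%s'> %s voxels, spacing %s mm (%s)\n",
    x$source_id, paste(dim(x$voxels), collapse = " x "),
    paste(signif(x$spacing, 4), collapse = " x "),
    paste(x$axes, collapse = ", ")
  ))
  invisible(x)
}

#' Lung mask container
#'
#' Binary voxel labels for lung parenchyma, congruent with a [ct_volume()].
#'
#' @param labels Logical 3-D array (or coercible 0/1 array).
#' @return An object of class `lung_mask`: the logical array with an attached
#'   voxel count.
#' @export
#' @examples
#' m <- lung_mask(array(c(TRUE, FALSE), c(2, 2, 2)))
#' n_voxels(m)
lung_mask <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("`labels` must be a 3-D array.", class = "focalindex_input_error")
  }
  storage <- array(as.logical(labels), dim = dim(labels))
  if (anyNA(storage)) {
    abort("Mask labels must be TRUE/FALSE (0/1) with no missing values.",
      class = "focalindex_input_error"
    )
  }
  structure(storage, class = c("lung_mask", "array"), voxel_count = sum(storage))
}

#' @rdname lung_mask
#' @param mask A `lung_mask`.
#' @export
n_voxels <- function(mask) {
  attr(mask, "voxel_count", exact = TRUE) %||% sum(mask)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf(
    "<lung_mask> %s grid, %d lung voxels\n",
    paste(dim(x), collapse = " x "), n_voxels(x)
  ))
  invisible(x)
}

.check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask))) {
    abort(
      sprintf(
        "Mask grid (%s) does not match volume grid (%s).",
        paste(dim(mask), collapse = "x"), paste(dim(volume$voxels), collapse = "x")
      ),
      class = "focalindex_congruence_error"
    )
  }
  invisible(TRUE)
}

#' Clip in-mask HU values to the analysable lung range
#'
#' Lung CT density runs from -1000 HU (pure gas) to +100 HU (non-aerated
#' tissue). Values outside that range inside the mask (calcifications, metal,
#' extreme noise) are clipped to the nearest bound rather than excluded, so the
#' mask voxel count keeps serving as the denominator of percentage histograms.
#' Out-of-mask voxels are untouched.
#'
#' @param volume A [ct_volume()].
#' @param mask A [lung_mask()] congruent with `volume`.
#' @return A new `ct_volume` (the input is not modified) with an attribute
#'   `clipped_count`: how many in-mask voxels were altered.
#' @export
#' @examples
#' v <- ct_volume(array(c(-1500, -500, 150, 0), c(1, 2, 2)))
#' m <- lung_mask(array(TRUE, c(1, 2, 2)))
#' clip_hu(v, m)$voxels
clip_hu <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lung_mask"))
  .check_congruent(volume, mask)
  out <- volume
  inside <- which(mask)
  vals <- out$voxels[inside]
  clipped <- pmin(.HU_MAX, pmax(.HU_MIN, vals))
  out$voxels[inside] <- clipped
  attr(out, "clipped_count") <- sum(clipped != vals)
  out
}

.check_hu_domain <- function(values, what = "HU values") {
  if (length(values) && (min(values) < .HU_MIN || max(values) > .HU_MAX)) {
    abort(
      sprintf(
        "%s outside [%d, %d]; run clip_hu() first.",
        what, .HU_MIN, .HU_MAX
      ),
      class = "focalindex_domain_error"
    )
  }
  invisible(TRUE)
}
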