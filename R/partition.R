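#' Select evenly spaced analysis slices along the craniocaudal axis
#'
#' Picks `n_slices` axial slices evenly distributed over the lung's
#' craniocaudal extent, always including the first and last lung-containing
#' slices. Ideal positions are the uniform real-valued grid between the two
#' extremes; each is rounded to the nearest slice (half rounded caudally) and
#' collisions are resolved by shifting caudally to the next free slice.
#'
#' @param volume A canonical [ct_volume()].
#' @param mask A congruent [lung_mask()].
#' @param n_slices Number of slices to select (default 18).
#' @return A `slice_selection`: list with `indices` (strictly increasing slice
#'   indices) and `slice_thickness` (mm along the craniocaudal axis).
#' @export
select_slices <- function(volume, mask, n_slices = 18L) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lung_mask"))
  .check_congruent(volume, mask)
  n_slices <- as.integer(n_slices)
  has_lung <- apply(mask, 1, any)
  if (!any(has_lung)) {
    abort("Mask is empty; no lung-containing slices.",
      class = "focalindex_input_error"
    )
  }
  z0 <- which(has_lung)[1]
  z1 <- tail(which(has_lung), 1)
  extent <- z1 - z0 + 1L
  if (extent < n_slices) {
    abort(
      sprintf(
        "Lung craniocaudal extent (%d slices) is smaller than n_slices = %d.",
        extent, n_slices
      ),
      class = "focalindex_extent_error"
    )
  }
  ideal <- seq(z0, z1, length.out = n_slices)
  idx <- integer(n_slices)
  prev <- z0 - 1L
  for (i in seq_len(n_slices)) {
    cand <- as.integer(floor(ideal[i] + 0.5)) # round half caudally
    cand <- max(cand, prev + 1L) # shift caudally past collisions
    cand <- min(cand, z1 - (n_slices - i)) # keep room for remaining slices
    idx[i] <- cand
    prev <- cand
  }
  structure(
    list(indices = idx, slice_thickness = volume$spacing[1]),
    class = "slice_selection"
  )
}

#' @export
print.slice_selection <- function(x, ...) {
  cat(sprintf(
    "<slice_selection> %d slices (%s), thickness %g mm\n",
    length(x$indices), paste(range(x$indices), collapse = ".."), x$slice_thickness
  ))
  invisible(x)
}

#' Assign craniocaudal bands to selected slices
#'
#' Splits the ordered selection into three equal groups: the most cranial
#' third is apical, the middle third mediastinal, the most caudal third
#' diaphragmatic. With the default 18 slices this yields 6 per band.
#'
#' @param selection A [select_slices()] result, or an increasing integer
#'   vector of slice indices.
#' @return A tibble with columns `slice` and `cc_band`.
#' @export
assign_cc_bands <- function(selection) {
  indices <- if (inherits(selection, "slice_selection")) selection$indices else as.integer(selection)
  if (is.unsorted(indices, strictly = TRUE)) {
    abort("Slice indices must be strictly increasing.",
      class = "focalindex_input_error"
    )
  }
  n <- length(indices)
  if (n %% 3L != 0L) {
    abort(sprintf("Cannot split %d slices into three equal craniocaudal groups.", n),
      class = "focalindex_partition_error"
    )
  }
  tibble(
    slice = indices,
    cc_band = factor(rep(.CC_BANDS, each = n / 3L), levels = .CC_BANDS)
  )
}

# Gravitational band of in-mask voxels on one slice: the ventral-dorsal lung
# extent on that slice (voxel-centre coordinates, mm) is cut into three
# equal-length bands, half-open and ventral-closed, so a voxel exactly on a
# boundary joins the more dorsal band.
.grav_bands_slice <- function(slice_mask, dy, extent_range = NULL) {
  rows <- which(apply(slice_mask, 1, any))
  if (!length(rows)) return(NULL)
  y <- (rows - 1) * dy
  rng <- extent_range %||% range(y)
  L <- rng[2] - rng[1]
  band_of_row <- if (L <= 0) {
    rep(1L, length(rows))
  } else {
    b1 <- rng[1] + L / 3
    b2 <- rng[1] + 2 * L / 3
    ifelse(y < b1, 1L, ifelse(y < b2, 2L, 3L))
  }
  setNames(band_of_row, rows)
}

#' Assign gravitational bands to lung voxels on the selected slices
#'
#' For each selected slice the ventral-dorsal extent of the lung mask is
#' divided into three equal-length bands (ventral, medial, dorsal) and every
#' in-mask voxel is labelled by the band containing its anterior-posterior
#' coordinate. Spacing is uniform along the AP axis, so equal physical lengths
#' are computed in row-index units, which keeps boundaries independent of the
#' storage precision of header spacing. Bands are half-open and
#' ventral-closed: a voxel exactly on a boundary joins the more dorsal band.
#' With `extent = "global"` one extent computed over all selected slices is
#' used instead of per-slice extents.
#'
#' @inheritParams select_slices
#' @param selection A [select_slices()] result.
#' @param extent `"per-slice"` (default) or `"global"`.
#' @return A tibble with one row per in-mask voxel on a selected slice:
#'   columns `slice`, `ap_row`, `lr_col`, `grav_band`.
#' @export
assign_grav_bands <- function(volume, mask, selection, extent = c("per-slice", "global")) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lung_mask"))
  .check_congruent(volume, mask)
  extent <- match.arg(extent)
  indices <- selection$indices
  # Voxel spacing is uniform along the AP axis, so equal-length thirds in mm
  # coincide with thirds in row-index units; computing in index units keeps
  # band boundaries immune to the float32 truncation of on-disk spacing.
  dy <- 1
  global_range <- NULL
  if (extent == "global") {
    rows_any <- which(apply(mask[indices, , , drop = FALSE], 2, any))
    if (length(rows_any)) global_range <- range((rows_any - 1) * dy)
  }
  nz <- dim(mask)[1]
  ny <- dim(mask)[2]
  per_slice <- lapply(indices, function(s) {
    slice_mask <- mask[s, , , drop = TRUE]
    idx <- which(slice_mask)
    if (!length(idx)) {
      warn(sprintf("Selected slice %d contains no lung voxels; skipped.", s),
        class = "focalindex_empty_slice_warning"
      )
      return(NULL)
    }
    ap_row <- ((idx - 1L) %% ny) + 1L
    band_of_row <- .grav_band_codes(ap_row, dy, global_range)
    tibble(
      slice = s,
      ap_row = ap_row,
      lr_col = ((idx - 1L) %/% ny) + 1L,
      # linear index into the full 3-D array, for fast voxel lookup
      .lin = s + nz * (idx - 1L),
      grav_code = band_of_row
    )
  })
  out <- dplyr::bind_rows(per_slice)
  out$grav_band <- structure(out$grav_code, levels = .GRAV_BANDS, class = "factor")
  out
}

# integer gravitational band (1 = ventral, 2 = medial, 3 = dorsal) of each
# voxel given its AP row; extent from the rows present unless overridden
.grav_band_codes <- function(ap_row, dy, extent_range = NULL) {
  y <- (ap_row - 1) * dy
  rng <- extent_range %||% range(y)
  L <- rng[2] - rng[1]
  if (L <= 0) return(rep(1L, length(ap_row)))
  b1 <- rng[1] + L / 3
  b2 <- rng[1] + 2 * L / 3
  1L + (y >= b1) + (y >= b2)
}

#' Build the nine-region map
#'
#' Composes the craniocaudal bands of the selected slices with the
#' gravitational bands of their lung voxels into nine three-dimensional
#' regions of interest. Every in-mask voxel on a selected slice belongs to
#' exactly one ROI; empty ROIs are recorded as warnings in the result.
#'
#' @inheritParams assign_grav_bands
#' @return A `region_map`: list with `roi` (integer label array, codes per
#'   [roi_table()], 0 outside), `counts` (tibble `roi_code`, `roi_id`,
#'   `grav_band`, `cc_band`, `n_voxels`), `voxels` (per-voxel tibble),
#'   `selection`, and `warnings` (character).
#' @export
build_region_map <- function(volume, mask, selection, extent = c("per-slice", "global")) {
  extent <- match.arg(extent)
  cc <- assign_cc_bands(selection)
  vox <- assign_grav_bands(volume, mask, selection, extent = extent)
  cc_code <- match(cc$cc_band, .CC_BANDS)[match(vox$slice, cc$slice)]
  vox$cc_band <- structure(cc_code, levels = .CC_BANDS, class = "factor")
  vox$roi_code <- (vox$grav_code - 1L) * 3L + cc_code
  roi <- array(0L, dim(mask))
  roi[vox$.lin] <- vox$roi_code
  counts <- roi_table()
  counts$n_voxels <- tabulate(vox$roi_code, nbins = 9L)
  empty <- counts$roi_id[counts$n_voxels == 0L]
  warnings <- character(0)
  if (length(empty)) {
    warnings <- sprintf("ROI '%s' contains no voxels.", empty)
    warn(paste(warnings, collapse = " "), class = "focalindex_empty_roi_warning")
  }
  structure(
    list(
      roi = roi, counts = counts, voxels = vox,
      selection = selection, warnings = warnings
    ),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf(
    "<region_map> 9 ROIs over %d selected slices, %d lung voxels\n",
    length(x$selection$indices), sum(x$counts$n_voxels)
  ))
  print(x$counts)
  invisible(x)
}
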