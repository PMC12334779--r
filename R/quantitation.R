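#' Gas and tissue fractions of a voxel
#'
#' Standard quantitative-CT decomposition of a clipped HU value: the gas
#' fraction is `-HU/1000` for HU in `[-1000, 0]` and 0 above water density;
#' the tissue fraction is its complement, so the two always sum to 1.
#'
#' @param hu Numeric HU values in `[-1000, +100]`.
#' @return A tibble with columns `hu`, `gas_fraction`, `tissue_fraction`.
#' @export
#' @examples
#' voxel_fractions(c(-1000, -500, 0, 100))
voxel_fractions <- function(hu) {
  hu <- as.numeric(hu)
  .check_hu_domain(hu)
  gas <- pmax(0, -hu / 1000)
  tibble(hu = hu, gas_fraction = gas, tissue_fraction = 1 - gas)
}

# density in g/ml of a clipped HU value: (HU + 1000)/1000, i.e. 0 for pure
# gas, 1 for water, up to 1.1 at +100.
.hu_density <- function(hu) (hu + 1000) / 1000

#' Per-slice gas volume and lung weight
#'
#' For each requested axial slice, sums in-mask voxel volumes weighted by the
#' gas fraction (gas ml) and by tissue density `(HU + 1000)/1000` g/ml
#' (weight g).
#'
#' @param volume A clipped, canonical [ct_volume()].
#' @param mask A congruent [lung_mask()].
#' @param slices Integer slice indices; default all slices.
#' @return A tibble: `slice`, `n_voxels`, `gas_ml`, `weight_g`.
#' @export
slice_quantities <- function(volume, mask, slices = NULL) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lung_mask"))
  .check_congruent(volume, mask)
  slices <- if (is.null(slices)) seq_len(dim(mask)[1]) else as.integer(slices)
  voxel_ml <- prod(volume$spacing) / 1000
  purrr::map_dfr(slices, function(s) {
    inside <- mask[s, , , drop = TRUE]
    hu <- volume$voxels[s, , , drop = TRUE][inside]
    .check_hu_domain(hu, "In-mask HU values")
    tibble(
      slice = s,
      n_voxels = length(hu),
      gas_ml = voxel_ml * sum(pmax(0, -hu / 1000)),
      weight_g = voxel_ml * sum(.hu_density(hu))
    )
  })
}

#' Whole-lung gas volume and weight by interpolation
#'
#' Gas and weight measured on the analysed slices are linearly interpolated
#' across every intervening lung slice; beyond the outermost analysed slices
#' the nearest measured value is held (zero-order) to the ends of the lung
#' extent. Totals are the sums of the interpolated per-slice values; at
#' analysed slices the interpolant equals the measurement, so analysing all
#' slices reproduces the direct sum.
#'
#' @param per_slice A tibble from [slice_quantities()] for the analysed
#'   slices (>= 2 rows).
#' @param lung_slices Integer vector of all lung-containing slice indices.
#' @return A `lung_quantitation` object: list with `gas_volume_ml`,
#'   `lung_weight_g`, `per_slice` (tibble `slice`, `analysed`, `gas_ml`,
#'   `weight_g`) and `method = "whole-lung-interpolated"`.
#' @export
whole_lung_quantitation <- function(per_slice, lung_slices) {
  stopifnot(is.data.frame(per_slice))
  if (nrow(per_slice) < 2) {
    abort("Interpolation needs at least two analysed slices.",
      class = "focalindex_support_error"
    )
  }
  lung_slices <- sort(unique(as.integer(lung_slices)))
  gas <- approx(per_slice$slice, per_slice$gas_ml, xout = lung_slices, rule = 2)$y
  wt <- approx(per_slice$slice, per_slice$weight_g, xout = lung_slices, rule = 2)$y
  structure(
    list(
      gas_volume_ml = sum(gas),
      lung_weight_g = sum(wt),
      per_slice = tibble(
        slice = lung_slices,
        analysed = lung_slices %in% per_slice$slice,
        gas_ml = gas,
        weight_g = wt
      ),
      method = "whole-lung-interpolated"
    ),
    class = "lung_quantitation"
  )
}

#' @export
print.lung_quantitation <- function(x, ...) {
  cat(sprintf(
    "<lung_quantitation> gas %.1f ml, weight %.1f g over %d slices (%s)\n",
    x$gas_volume_ml, x$lung_weight_g, nrow(x$per_slice), x$method
  ))
  invisible(x)
}

#' @export
glance.lung_quantitation <- function(x, ...) {
  tibble(
    gas_volume_ml = x$gas_volume_ml,
    lung_weight_g = x$lung_weight_g,
    n_slices = nrow(x$per_slice),
    n_analysed = sum(x$per_slice$analysed),
    method = x$method
  )
}
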