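#' The 5-HU histogram grid
#'
#' The analysable HU domain `[-1000, +100]` is covered by 220 bins of width
#' 5 HU. Bins are half-open `[left, left + 5)` except the final bin
#' `[95, 100]`, which is closed so the upper clip bound is counted.
#'
#' @return A tibble with columns `bin`, `bin_left`, `bin_right`.
#' @export
#' @examples
#' nrow(hu_bins())
hu_bins <- function() {
  left <- .HU_MIN + .BIN_WIDTH * (seq_len(.N_BINS) - 1)
  tibble(bin = seq_len(.N_BINS), bin_left = left, bin_right = left + .BIN_WIDTH)
}

.bin_index <- function(values) {
  pmin(.N_BINS, as.integer(floor((values - .HU_MIN) / .BIN_WIDTH)) + 1L)
}

#' Normalised HU distribution profile of one voxel collection
#'
#' Bins clipped HU values on the standard 5-HU grid and normalises counts to
#' percent of the voxel total, so a non-empty profile sums to 100. An empty
#' input yields an all-zero profile flagged empty (`attr(, "empty")`), which
#' downstream consumers must handle explicitly.
#'
#' @param values Numeric HU values, already within `[-1000, +100]`
#'   (see [clip_hu()]); out-of-domain values raise a domain error.
#' @param roi_id Label attached to the profile rows.
#' @return A 220-row tibble: `roi_id`, `bin_left`, `bin_right`, `percent`,
#'   `n_voxels`; attribute `empty` is `TRUE` when `values` is empty.
#' @export
#' @examples
#' p <- hu_profile(rep(-900, 10))
#' sum(p$percent)
hu_profile <- function(values, roi_id = "roi") {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  .check_hu_domain(values)
  n <- length(values)
  counts <- if (n) tabulate(.bin_index(values), nbins = .N_BINS) else rep(0L, .N_BINS)
  out <- hu_bins()
  out$roi_id <- roi_id
  out$percent <- if (n) 100 * counts / n else rep(0, .N_BINS)
  out$n_voxels <- n
  out <- out[, c("roi_id", "bin", "bin_left", "bin_right", "percent", "n_voxels")]
  attr(out, "empty") <- n == 0L
  out
}

#' Regional HU distribution profiles
#'
#' Computes the normalised HU profile of each of the nine regions of interest.
#'
#' @param volume A clipped, canonical [ct_volume()].
#' @param mask A congruent [lung_mask()].
#' @param region_map A [build_region_map()] result.
#' @return A tibble with one row per ROI and bin: `roi_code`, `roi_id`,
#'   `grav_band`, `cc_band`, `bin`, `bin_left`, `bin_right`, `percent`,
#'   `n_voxels`. Empty ROIs carry zero rows of mass (`n_voxels = 0`).
#' @export
hu_profiles <- function(volume, mask, region_map) {
  stopifnot(inherits(volume, "ct_volume"), inherits(region_map, "region_map"))
  .check_congruent(volume, mask)
  vox <- region_map$voxels
  hu <- volume$voxels[vox$.lin]
  .check_hu_domain(hu, "In-mask HU values")
  info <- roi_table()
  profiles <- purrr::map_dfr(seq_len(9L), function(code) {
    p <- hu_profile(hu[vox$roi_code == code], roi_id = info$roi_id[code])
    p$roi_code <- code
    p
  })
  dplyr::select(
    dplyr::left_join(profiles, info[, c("roi_code", "grav_band", "cc_band")],
      by = "roi_code"
    ),
    "roi_code", "roi_id", "grav_band", "cc_band",
    "bin", "bin_left", "bin_right", "percent", "n_voxels"
  )
}

#' Aeration compartments of HU profiles
#'
#' Sums profile mass over the standard aeration compartments: hyperaerated
#' `[-1000, -800)`, normally aerated `[-800, -500)`, poorly aerated
#' `[-500, -100)` and non-aerated `[-100, +100]`. The boundary convention is
#' half-open at interior boundaries (a 5-HU bin belongs to the compartment
#' containing its left edge), configurable through the `hyper_upper` and
#' `nonaer_lower` cut points. Empty ROIs yield `NA` percentages rather than
#' silent zeros.
#'
#' @param profiles A profile tibble from [hu_profiles()] (or [hu_profile()]).
#' @param hyper_upper Upper HU bound of the hyperaerated compartment
#'   (default -800).
#' @param nonaer_lower Lower HU bound of the non-aerated compartment
#'   (default -100).
#' @return A tibble per ROI: `roi_id`, `n_voxels`, `hyper_percent`,
#'   `normal_percent`, `poor_percent`, `nonaer_percent`.
#' @export
aeration_summary <- function(profiles, hyper_upper = -800, nonaer_lower = -100) {
  stopifnot(all(c("roi_id", "bin_left", "percent", "n_voxels") %in% names(profiles)))
  dplyr::summarise(
    dplyr::group_by(profiles, .data$roi_id),
    n_voxels = .data$n_voxels[1],
    hyper_percent = ifelse(.data$n_voxels[1] == 0, NA_real_,
      sum(.data$percent[.data$bin_left < hyper_upper])
    ),
    normal_percent = ifelse(.data$n_voxels[1] == 0, NA_real_,
      sum(.data$percent[.data$bin_left >= hyper_upper & .data$bin_left < -500])
    ),
    poor_percent = ifelse(.data$n_voxels[1] == 0, NA_real_,
      sum(.data$percent[.data$bin_left >= -500 & .data$bin_left < nonaer_lower])
    ),
    nonaer_percent = ifelse(.data$n_voxels[1] == 0, NA_real_,
      sum(.data$percent[.data$bin_left >= nonaer_lower])
    ),
    .groups = "drop"
  )
}
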