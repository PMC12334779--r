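#' The focal index
#'
#' Scores the focality of lung injury as the non-overlapping area between the
#' normalised HU distribution curves of the ventral-apical (VA) and
#' dorsal-diaphragmatic (DD) regions. With each curve treated as a probability
#' density over the HU domain, the index is
#' \deqn{FI = 100 \int |f_{VA}(x) - f_{DD}(x)| \, dx
#'          = 100 \sum_b |p_{VA}(b) - p_{DD}(b)|,}
#' the discrete sum running over the 5-HU bins. This equals 200 times the
#' total-variation distance between the two distributions: 0 means complete
#' overlap (homogeneous aeration, no focality), 200 means disjoint support
#' (maximal regional difference, high focality). Since profiles store percent
#' per bin, the index is simply the summed absolute percent difference.
#'
#' @param profiles Either a multi-ROI profile tibble from [hu_profiles()], or
#'   the VA profile alone (then `dd` must be a profile tibble too).
#' @param va,dd ROI ids of the two compared regions when `profiles` holds
#'   several ROIs; or, if `profiles` is a single profile, `dd` is the second
#'   profile.
#' @return A `focal_index` object: list with `value` (in `[0, 200]`),
#'   `overlap_percent` (`100 - value/2`, the shared probability mass as
#'   percent), and the two profiles used.
#' @export
#' @examples
#' va <- hu_profile(rep(-900, 50), "ventral_apical")
#' dd <- hu_profile(rep(0, 50), "dorsal_diaphragmatic")
#' focal_index(va, dd)$value
focal_index <- function(profiles, dd = NULL, va = "ventral_apical") {
  if (is.null(dd)) {
    dd_id <- "dorsal_diaphragmatic"
    va_p <- profiles[profiles$roi_id == va, , drop = FALSE]
    dd_p <- profiles[profiles$roi_id == dd_id, , drop = FALSE]
    if (!nrow(va_p) || !nrow(dd_p)) {
      abort(
        sprintf("Profiles for '%s' and '%s' not found in `profiles`.", va, dd_id),
        class = "focalindex_input_error"
      )
    }
  } else if (is.character(dd)) {
    va_p <- profiles[profiles$roi_id == va, , drop = FALSE]
    dd_p <- profiles[profiles$roi_id == dd, , drop = FALSE]
  } else {
    va_p <- profiles
    dd_p <- dd
  }
  .focal_index_profiles(va_p, dd_p)
}

.focal_index_profiles <- function(va_p, dd_p) {
  for (p in list(va_p, dd_p)) {
    if (nrow(p) != .N_BINS) {
      abort("Profiles must live on the standard 220-bin grid.",
        class = "focalindex_grid_error"
      )
    }
  }
  if (!isTRUE(all.equal(va_p$bin_left, dd_p$bin_left))) {
    abort("Profile bin grids do not match.", class = "focalindex_grid_error")
  }
  if (va_p$n_voxels[1] == 0 || dd_p$n_voxels[1] == 0) {
    abort(
      "Focal index is undefined for empty regions; refuse to treat them as zero curves.",
      class = "focalindex_empty_profile_error"
    )
  }
  value <- sum(abs(va_p$percent - dd_p$percent))
  structure(
    list(
      value = value,
      overlap_percent = 100 - value / 2,
      va_profile = va_p,
      dd_profile = dd_p
    ),
    class = "focal_index"
  )
}

#' @export
print.focal_index <- function(x, ...) {
  cat(sprintf(
    "<focal_index> %.2f (0 = homogeneous, 200 = fully separated); overlap %.2f%%\n",
    x$value, x$overlap_percent
  ))
  invisible(x)
}

#' @export
tidy.focal_index <- function(x, ...) {
  tibble(
    focal_index = x$value,
    overlap_percent = x$overlap_percent,
    va_n_voxels = x$va_profile$n_voxels[1],
    dd_n_voxels = x$dd_profile$n_voxels[1]
  )
}

#' Pairwise focal-index matrix over the nine regions
#'
#' Diagnostic generalisation of the score: the focal index between every pair
#' of regional profiles. The matrix is symmetric with a zero diagonal; rows
#' and columns involving empty regions are `NA`.
#'
#' @param profiles A profile tibble from [hu_profiles()].
#' @return A 9 x 9 symmetric numeric matrix with ROI ids as dimnames.
#' @export
pairwise_focal_matrix <- function(profiles) {
  ids <- roi_table()$roi_id
  split_p <- lapply(ids, function(id) profiles[profiles$roi_id == id, , drop = FALSE])
  names(split_p) <- ids
  m <- matrix(NA_real_, 9, 9, dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    if (!nrow(split_p[[i]]) || split_p[[i]]$n_voxels[1] == 0) next
    m[i, i] <- 0
    for (j in seq_len(i - 1L)) {
      if (!nrow(split_p[[j]]) || split_p[[j]]$n_voxels[1] == 0) next
      v <- .focal_index_profiles(split_p[[i]], split_p[[j]])$value
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}
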