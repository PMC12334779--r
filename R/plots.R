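#' Plot the nine regional HU distribution profiles
#'
#' One panel per region of interest (gravitational bands as rows, craniocaudal
#' bands as columns), percent of regional voxels per 5-HU bin.
#'
#' @param profiles A profile tibble from [hu_profiles()].
#' @return A ggplot object.
#' @export
plot_hu_profiles <- function(profiles) {
  ggplot2::ggplot(
    profiles,
    ggplot2::aes(x = .data$bin_left + .BIN_WIDTH / 2, y = .data$percent)
  ) +
    ggplot2::geom_col(width = .BIN_WIDTH, fill = "grey35") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$grav_band),
      cols = ggplot2::vars(.data$cc_band)
    ) +
    ggplot2::labs(
      x = "Hounsfield units", y = "% of regional voxels",
      title = "Regional HU distribution profiles"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn focal_index Superimposed VA/DD curves with the non-overlapping
#'   area shaded; the focal index is the shaded area summed over bins.
#' @param object A `focal_index` result.
#' @param ... Unused.
#' @export
autoplot.focal_index <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$va_profile, region = "ventral apical"),
    dplyr::mutate(object$dd_profile, region = "dorsal diaphragmatic")
  )
  ribbon <- tibble(
    x = object$va_profile$bin_left + .BIN_WIDTH / 2,
    lo = pmin(object$va_profile$percent, object$dd_profile$percent),
    hi = pmax(object$va_profile$percent, object$dd_profile$percent)
  )
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = ribbon,
      ggplot2::aes(x = .data$x, ymin = .data$lo, ymax = .data$hi),
      fill = "grey80"
    ) +
    ggplot2::geom_line(
      data = d,
      ggplot2::aes(
        x = .data$bin_left + .BIN_WIDTH / 2, y = .data$percent,
        colour = .data$region
      )
    ) +
    ggplot2::labs(
      x = "Hounsfield units", y = "% of regional voxels",
      colour = NULL,
      title = sprintf("Focal index %.1f (overlap %.1f%%)", object$value, object$overlap_percent)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cohort focal-index distribution
#'
#' @param cohort The `cohort` tibble from [run_cohort()] (needs a
#'   `focal_index` column).
#' @param binwidth Histogram bin width on the 0-200 scale.
#' @return A ggplot object.
#' @export
plot_cohort_focal_index <- function(cohort, binwidth = 10) {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$focal_index)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, fill = "grey35") +
    ggplot2::coord_cartesian(xlim = c(0, 200)) +
    ggplot2::labs(
      x = "Focal index", y = "Scans",
      title = "Focal index across the cohort"
    ) +
    ggplot2::theme_minimal()
}
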