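#' Truncated-normal mixture law over the HU domain
#'
#' Regional HU values in phantoms are drawn from a mixture of normals and then
#' clipped to `[-1000, +100]`, exactly as [clip_hu()] treats acquired data, so
#' out-of-range tail mass collapses onto the domain bounds (and hence into the
#' first/last 5-HU bins).
#'
#' @param means,sds,weights Component parameters; `weights` must sum to 1.
#' @return An `hu_law` object.
#' @export
#' @examples
#' law <- hu_law(c(-850, -100), c(10, 10), c(0.7, 0.3))
#' sum(binned_percent(law))
hu_law <- function(means, sds, weights = rep(1 / length(means), length(means))) {
  stopifnot(length(means) == length(sds), length(means) == length(weights))
  if (any(sds <= 0) || any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("Law needs positive SDs and nonnegative weights summing to 1.",
      class = "focalindex_config_error"
    )
  }
  structure(
    list(means = as.numeric(means), sds = as.numeric(sds), weights = as.numeric(weights)),
    class = "hu_law"
  )
}

#' @export
print.hu_law <- function(x, ...) {
  cat(
    "<hu_law> components (mean HU, sd, weight):\n",
    paste(sprintf(
      "  (%.1f, %.1f, %.3f)", x$means, x$sds, x$weights
    ), collapse = "\n"), "\n"
  )
  invisible(x)
}

# mixture cdf before clipping
.law_cdf <- function(law, q) {
  rowSums(vapply(
    seq_along(law$means),
    function(k) law$weights[k] * pnorm(q, law$means[k], law$sds[k]),
    numeric(length(q))
  ))
}

#' @rdname hu_law
#' @param law An `hu_law`.
#' @param n Number of draws.
#' @param noise_sd Gaussian acquisition noise added before clipping.
#' @export
sample_law <- function(law, n, noise_sd = 0) {
  comp <- sample.int(length(law$weights), n, replace = TRUE, prob = law$weights)
  x <- rnorm(n, law$means[comp], law$sds[comp])
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  pmin(.HU_MAX, pmax(.HU_MIN, x))
}

#' @rdname hu_law
#' @details `binned_percent()` returns the exact probability mass of the
#'   clipped law in each 5-HU bin, as percent: interior bins integrate the
#'   mixture density, while mass clipped at the domain bounds is lumped into
#'   the first and last bins. `noise_sd` convolves each component with
#'   independent Gaussian noise before clipping.
#' @export
binned_percent <- function(law, noise_sd = 0) {
  total <- hu_law(law$means, sqrt(law$sds^2 + noise_sd^2), law$weights)
  edges <- c(.HU_MIN, hu_bins()$bin_right)
  cdf <- .law_cdf(total, edges)
  p <- diff(cdf)
  p[1] <- p[1] + cdf[1] # mass clipped up to -1000
  p[.N_BINS] <- p[.N_BINS] + 1 - cdf[.N_BINS + 1] # mass clipped down to +100
  100 * p
}

#' Analytic focal index between two generating laws
#'
#' Ground-truth focal index of a phantom: both laws are projected exactly onto
#' the 5-HU grid (clipped-tail mass included) and the summed absolute percent
#' difference is returned - the value the empirical index converges to as the
#' regional voxel count grows.
#'
#' @param law_va,law_dd [hu_law()] objects for the ventral-apical and
#'   dorsal-diaphragmatic regions.
#' @param noise_sd Acquisition noise convolved into both laws.
#' @return The focal index in `[0, 200]`.
#' @export
#' @examples
#' analytic_focal_index(hu_law(-850, 10), hu_law(-100, 10))
analytic_focal_index <- function(law_va, law_dd, noise_sd = 0) {
  sum(abs(binned_percent(law_va, noise_sd) - binned_percent(law_dd, noise_sd)))
}

#' Phantom configuration
#'
#' Describes a synthetic thoracic CT: two lung ellipsoids inside a soft-tissue
#' body on an air background, with per-region HU laws interpolating between a
#' homogeneous, fully aerated lung (`phi = 0`) and complete
#' ventral-aerated/dorsal-consolidated separation (`phi = 1`). Each region's
#' law is a two-class mixture - an aerated material class and a consolidated
#' material class - whose consolidated weight is `phi * g`, where `g` in
#' `[0, 1]` is the region's position along the combined ventral-to-dorsal and
#' apex-to-diaphragm gradient (weights `grav_weight`/`cc_weight`). Class
#' means/SDs model uniform phantom materials; `noise_sd` models acquisition
#' noise. The default grid is sized so every region of interest holds at
#' least 1e5 voxels.
#'
#' @param phi Focality parameter in `[0, 1]`.
#' @param scale In-plane scale factor; `scale = 0.25` gives a small phantom
#'   for quick experimentation.
#' @param n_slices Number of axial slices (default 18, the analysis count).
#' @param spacing Voxel spacing, mm.
#' @param aerated_mean,consolidated_mean,class_sd HU law of the two material
#'   classes.
#' @param noise_sd Acquisition noise SD, HU.
#' @param grav_weight,cc_weight Relative contribution of the gravitational and
#'   craniocaudal position to the gradient coordinate `g`.
#' @param body_hu,background_hu HU of the body and the exterior air.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(phi = 0.5, scale = 1, n_slices = 18L,
                           spacing = c(12, 0.7, 0.7),
                           aerated_mean = -850, consolidated_mean = -50,
                           class_sd = 10, noise_sd = 6,
                           grav_weight = 0.5, cc_weight = 0.5,
                           body_hu = 40, background_hu = -1000) {
  if (phi < 0 || phi > 1) {
    abort("`phi` must lie in [0, 1].", class = "focalindex_config_error")
  }
  ay <- 115 * scale # ventral-dorsal semi-axis, voxels
  bx <- 165 * scale # left-right semi-axis, voxels
  ny <- as.integer(ceiling(2 * ay) + 40)
  nx <- as.integer(2 * ceiling(2 * bx) + 56)
  nz <- as.integer(n_slices)
  cz <- (nz - 1) / 2 + 0.3 # craniocaudal semi-axis, voxels
  centre_z <- (nz + 1) / 2
  centres <- rbind(
    c(centre_z, ny / 2, nx / 2 - bx - 9),
    c(centre_z, ny / 2, nx / 2 + bx + 9)
  )
  structure(
    list(
      grid_shape = c(nz, ny, nx), spacing = as.numeric(spacing),
      lung_centres = centres, # voxel-index coordinates (axis order as grid)
      lung_semiaxes = c(cz, ay, bx), # voxel-index units
      phi = phi,
      aerated_mean = aerated_mean, consolidated_mean = consolidated_mean,
      class_sd = class_sd, noise_sd = noise_sd,
      grav_weight = grav_weight, cc_weight = cc_weight,
      body_hu = body_hu, background_hu = background_hu
    ),
    class = "phantom_config"
  )
}

# Region gradient coordinate g in [0, 1]: 0 at ventral-apical, 1 at
# dorsal-diaphragmatic.
.region_gradient <- function(config) {
  info <- roi_table()
  grav_pos <- (match(as.character(info$grav_band), .GRAV_BANDS) - 1) / 2
  cc_pos <- (match(as.character(info$cc_band), .CC_BANDS) - 1) / 2
  w <- c(config$grav_weight, config$cc_weight)
  as.numeric((w[1] * grav_pos + w[2] * cc_pos) / sum(w))
}

.region_law <- function(config, g) {
  alpha <- config$phi * g
  hu_law(
    c(config$aerated_mean, config$consolidated_mean),
    c(config$class_sd, config$class_sd),
    c(1 - alpha, alpha)
  )
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

#' Generate a synthetic thoracic CT phantom
#'
#' Builds the lung mask from the configured ellipsoids, partitions it with the
#' package's own nine-region rule, draws every lung voxel independently from
#' its region's HU law (plus acquisition noise, then clipping), and embeds the
#' lungs in a soft-tissue body on an air background. The same seed always
#' reproduces the phantom bit-exactly.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed fully determining the phantom.
#' @return A list of class `ct_phantom`: `volume` ([ct_volume()]), `mask`
#'   ([lung_mask()]) and `truth` - the generating laws per region (tibble),
#'   the analytic focal index, the region map used for generation, and the
#'   config/seed.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  # ellipsoids must stay inside the physical grid box (half-voxel margins)
  for (l in 1:2) {
    lo <- config$lung_centres[l, ] - config$lung_semiaxes
    hi <- config$lung_centres[l, ] + config$lung_semiaxes
    if (any(lo < 0.5) || any(hi > dims + 0.5)) {
      abort("Lung ellipsoid overlaps the grid boundary.",
        class = "focalindex_geometry_error"
      )
    }
  }
  mask_arr <- array(FALSE, dims)
  body_arr <- array(FALSE, dims)
  ys <- seq_len(dims[2])
  xs <- seq_len(dims[3])
  body_ay <- dims[2] / 2 - 8
  body_bx <- dims[3] / 2 - 8
  body_q <- outer(
    ((ys - dims[2] / 2) / body_ay)^2,
    ((xs - dims[3] / 2) / body_bx)^2, "+"
  ) <= 1
  lung_q <- lapply(1:2, function(l) {
    ctr <- config$lung_centres[l, ]
    outer(
      ((ys - ctr[2]) / config$lung_semiaxes[2])^2,
      ((xs - ctr[3]) / config$lung_semiaxes[3])^2, "+"
    )
  })
  for (s in seq_len(dims[1])) {
    in_lung <- matrix(FALSE, dims[2], dims[3])
    for (l in 1:2) {
      f <- 1 - ((s - config$lung_centres[l, 1]) / config$lung_semiaxes[1])^2
      if (f <= 0) next
      in_lung <- in_lung | (lung_q[[l]] <= f)
    }
    mask_arr[s, , ] <- in_lung
    body_arr[s, , ] <- body_q
  }
  mask <- lung_mask(mask_arr)
  voxels <- array(config$background_hu, dims)
  voxels[body_arr] <- config$body_hu
  volume <- ct_volume(voxels, spacing = config$spacing, source_id = sprintf("phantom_seed%d", seed))

  selection <- select_slices(volume, mask, n_slices = min(18L, dims[1]))
  rmap <- build_region_map(volume, mask, selection)
  g <- .region_gradient(config)
  laws <- lapply(seq_len(9L), function(code) .region_law(config, g[code]))

  vox <- rmap$voxels
  .with_seed(seed, {
    for (code in seq_len(9L)) {
      lin <- vox$.lin[vox$roi_code == code]
      if (!length(lin)) next
      volume$voxels[lin] <- sample_law(laws[[code]], length(lin), noise_sd = config$noise_sd)
    }
    # lung voxels off the selected slices (only when nz > 18): nearest
    # selected slice's craniocaudal band, per-slice gravitational thirds
    leftover <- which(mask_arr & rmap$roi == 0L, arr.ind = TRUE)
    if (nrow(leftover)) {
      cc_of <- assign_cc_bands(selection)
      for (s in unique(leftover[, 1])) {
        nearest <- cc_of$cc_band[which.min(abs(cc_of$slice - s))]
        bands <- .grav_bands_slice(mask_arr[s, , , drop = TRUE], 1)
        rows <- leftover[leftover[, 1] == s, , drop = FALSE]
        codes <- .roi_code(.GRAV_BANDS[bands[as.character(rows[, 2])]], nearest)
        for (code in unique(codes)) {
          sel <- rows[codes == code, , drop = FALSE]
          volume$voxels[sel] <- sample_law(laws[[code]], nrow(sel), noise_sd = config$noise_sd)
        }
      }
    }
  })

  info <- roi_table()
  truth_laws <- tibble(
    roi_code = info$roi_code, roi_id = info$roi_id, gradient = g,
    consolidated_weight = config$phi * g,
    law = laws
  )
  va_law <- laws[[.roi_code("ventral", "apical")]]
  dd_law <- laws[[.roi_code("dorsal", "diaphragmatic")]]
  structure(
    list(
      volume = volume, mask = mask,
      truth = list(
        laws = truth_laws,
        analytic_fi = analytic_focal_index(va_law, dd_law, noise_sd = config$noise_sd),
        region_map = rmap,
        config = config,
        seed = seed
      )
    ),
    class = "ct_phantom"
  )
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf(
    "<ct_phantom> phi = %.2f, analytic focal index %.2f, %d lung voxels\n",
    x$truth$config$phi, x$truth$analytic_fi, n_voxels(x$mask)
  ))
  invisible(x)
}
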