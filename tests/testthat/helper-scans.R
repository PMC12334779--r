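# Small geometric scans built in code for partition/quantitation tests.

# A cuboid "lung" of constant HU inside a larger grid.
cuboid_scan <- function(nz = 18, ny = 40, nx = 30,
                        slices = seq_len(nz), rows = 5:34, cols = 4:27,
                        hu = -500, background = -1000, spacing = c(1.5, 1, 1)) {
  vox <- array(background, c(nz, ny, nx))
  m <- array(FALSE, c(nz, ny, nx))
  m[slices, rows, cols] <- TRUE
  vox[m] <- hu
  list(
    volume = ct_volume(vox, spacing = spacing, source_id = "cuboid"),
    mask = lung_mask(m)
  )
}

# Two-ellipsoid lung phantom in a soft-tissue body for segmentation tests.
segmentation_phantom <- function(n = 48, lung_hu = -850, body_hu = 50,
                                 inclusion = NULL, inclusion_hu = -400) {
  vox <- array(-1000, c(n, n, n))
  mask <- array(FALSE, c(n, n, n))
  centre <- (n + 1) / 2
  body_r <- n / 2 - 3
  semi <- c(n / 2 - 6, n / 6, n / 8)
  centres <- list(c(centre, centre, centre - n / 5), c(centre, centre, centre + n / 5))
  coords <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  body <- ((coords$y - centre)^2 + (coords$x - centre)^2) <= body_r^2
  vox[as.matrix(coords[body, ])] <- body_hu
  for (ctr in centres) {
    inside <- ((coords$z - ctr[1]) / semi[1])^2 +
      ((coords$y - ctr[2]) / semi[2])^2 +
      ((coords$x - ctr[3]) / semi[3])^2 <= 1
    vox[as.matrix(coords[inside, ])] <- lung_hu
    mask[as.matrix(coords[inside, ])] <- TRUE
  }
  if (!is.null(inclusion)) {
    vox[inclusion] <- inclusion_hu
  }
  # 3 mm isotropic so the lungs comfortably exceed the minimum component volume
  list(
    volume = ct_volume(vox, spacing = c(3, 3, 3), source_id = "segphantom"),
    truth = lung_mask(mask)
  )
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
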