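# Binary 3-D morphology on logical arrays, spacing-aware.
#
# Implemented with whole-array shifts so each operation is vectorised; kernels
# are balls in physical mm. Adequate for the voxel counts this package works
# with (segmentation phantoms and clinical lung grids).

# Shift a logical array by (dz, dy, dx), filling exposed planes with FALSE.
.shift3 <- function(x, d) {
  dims <- dim(x)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    n <- dims[k]
    if (d[k] >= 0) {
      src[[k]] <- seq_len(n - d[k])
      dst[[k]] <- seq_len(n - d[k]) + d[k]
    } else {
      src[[k]] <- seq_len(n + d[k]) - d[k]
      dst[[k]] <- seq_len(n + d[k])
    }
    if (length(src[[k]]) == 0) return(array(FALSE, dims))
  }
  out <- array(FALSE, dims)
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

.ball_offsets <- function(radius_mm, spacing) {
  r <- vapply(spacing, function(s) floor(radius_mm / s), numeric(1))
  grid <- expand.grid(
    dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3],
    KEEP.OUT.ATTRS = FALSE
  )
  d2 <- (grid$dz * spacing[1])^2 + (grid$dy * spacing[2])^2 + (grid$dx * spacing[3])^2
  as.matrix(grid[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

.dilate3 <- function(x, radius_mm, spacing) {
  offs <- .ball_offsets(radius_mm, spacing)
  out <- array(FALSE, dim(x))
  for (i in seq_len(nrow(offs))) out <- out | .shift3(x, offs[i, ])
  out
}

.erode3 <- function(x, radius_mm, spacing) !.dilate3(!x, radius_mm, spacing)

.close3 <- function(x, radius_mm, spacing) {
  if (radius_mm <= 0) return(x)
  .erode3(.dilate3(x, radius_mm, spacing), radius_mm, spacing)
}

# 6-connected component labelling by vectorised frontier growth. Returns an
# integer array (0 = background) and component sizes.
.label_components <- function(x) {
  labels <- array(0L, dim(x))
  remaining <- x
  offsets <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
  )
  lab <- 0L
  sizes <- integer(0)
  while (any(remaining)) {
    lab <- lab + 1L
    seed_idx <- which(remaining)[1]
    comp <- array(FALSE, dim(x))
    comp[seed_idx] <- TRUE
    frontier <- comp
    repeat {
      grown <- array(FALSE, dim(x))
      for (i in 1:6) grown <- grown | .shift3(frontier, offsets[i, ])
      grown <- grown & remaining & !comp
      if (!any(grown)) break
      comp <- comp | grown
      frontier <- grown
    }
    labels[comp] <- lab
    sizes <- c(sizes, sum(comp))
    remaining <- remaining & !comp
  }
  list(labels = labels, sizes = sizes)
}
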