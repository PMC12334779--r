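# Independent oracles, deliberately written with different machinery than the
# package internals.

# Brute-force focal index from raw voxel values: explicit per-bin counting
# (half-open bins, last closed) and 200 x total-variation distance.
brute_force_fi <- function(va_values, dd_values) {
  edges <- seq(-1000, 100, by = 5)
  count_bins <- function(x) {
    vapply(seq_len(220), function(b) {
      lo <- edges[b]
      hi <- edges[b + 1]
      if (b < 220) sum(x >= lo & x < hi) else sum(x >= lo & x <= hi)
    }, numeric(1))
  }
  pa <- count_bins(va_values) / length(va_values)
  pb <- count_bins(dd_values) / length(dd_values)
  200 * 0.5 * sum(abs(pa - pb))
}

# Fine-grid (0.1 HU) numeric projection of a normal-mixture law onto the 5-HU
# grid, clipping tail mass onto the end bins; uses densities, not CDFs.
fine_grid_percent <- function(law, noise_sd = 0) {
  sds <- sqrt(law$sds^2 + noise_sd^2)
  x <- seq(-2500, 1500, by = 0.1)
  f <- rep(0, length(x))
  for (k in seq_along(law$means)) {
    f <- f + law$weights[k] * dnorm(x, law$means[k], sds[k])
  }
  mass <- f * 0.1
  clipped <- pmin(100, pmax(-1000, x))
  bin <- pmin(220, floor((clipped + 1000) / 5) + 1)
  100 * as.numeric(tapply(mass, factor(bin, levels = 1:220), sum, default = 0))
}

# Random non-empty HU profile built from raw draws of a lumpy distribution.
random_hu_sample <- function(n = 2000) {
  centre <- runif(1, -950, 50)
  spread <- runif(1, 20, 250)
  pmin(100, pmax(-1000, rnorm(n, centre, spread)))
}
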