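test_that("the focal index hits its analytic endpoints", {
  set.seed(41)
  x <- random_hu_sample(3000)
  p <- hu_profile(x, "ventral_apical")
  expect_equal(focal_index(p, hu_profile(x, "dorsal_diaphragmatic"))$value, 0)

  va <- hu_profile(rep(-900, 100), "ventral_apical")
  dd <- hu_profile(rep(0, 100), "dorsal_diaphragmatic")
  res <- focal_index(va, dd)
  expect_equal(res$value, 200)
  expect_equal(res$overlap_percent, 0)

  # half-overlapping uniform densities: FI = 100 exactly
  va_u <- hu_profile(rep(seq(-997.5, -502.5, by = 5), each = 10), "ventral_apical")
  dd_u <- hu_profile(rep(seq(-747.5, -252.5, by = 5), each = 10), "dorsal_diaphragmatic")
  expect_equal(focal_index(va_u, dd_u)$value, 100)
})

test_that("focal index equals 200 x total variation from an independent oracle", {
  set.seed(42)
  for (i in 1:25) {
    a <- random_hu_sample(sample(200:3000, 1))
    b <- random_hu_sample(sample(200:3000, 1))
    fi <- focal_index(hu_profile(a, "ventral_apical"), hu_profile(b, "dorsal_diaphragmatic"))
    expect_equal(fi$value, brute_force_fi(a, b), tolerance = 1e-9)
    expect_equal(fi$overlap_percent + fi$value / 2, 100)
  }
})

test_that("the index is symmetric, scale invariant and satisfies the triangle bound", {
  set.seed(43)
  a <- random_hu_sample(1000)
  b <- random_hu_sample(1200)
  c_ <- random_hu_sample(800)
  pa <- hu_profile(a, "a")
  pb <- hu_profile(b, "b")
  pc <- hu_profile(c_, "c")
  fab <- focal_index(pa, pb)$value
  expect_equal(focal_index(pb, pa)$value, fab)
  # duplicating every voxel leaves the index unchanged
  expect_equal(focal_index(hu_profile(rep(a, 2), "a"), pb)$value, fab, tolerance = 1e-12)
  fac <- focal_index(pa, pc)$value
  fbc <- focal_index(pb, pc)$value
  expect_lte(fac, fab + fbc + 1e-12)
})

test_that("aggregating 1-HU bins to 5-HU bins never increases the index", {
  set.seed(44)
  for (i in 1:10) {
    a <- round(random_hu_sample(2000))
    b <- round(random_hu_sample(2000))
    # fine 1-HU index: direct total variation on integer HU values
    fine <- sapply(-1000:100, function(h) {
      abs(mean(a == h) - mean(b == h))
    })
    fi_fine <- 100 * sum(fine)
    fi_coarse <- focal_index(hu_profile(a, "a"), hu_profile(b, "b"))$value
    expect_lte(fi_coarse, fi_fine + 1e-9)
  }
})

test_that("degenerate inputs are refused", {
  p <- hu_profile(rep(-500, 10), "ventral_apical")
  empty <- hu_profile(numeric(0), "dorsal_diaphragmatic")
  expect_error(focal_index(p, empty), class = "focalindex_empty_profile_error")
  short <- p[1:100, ]
  expect_error(focal_index(short, short), class = "focalindex_grid_error")
})

test_that("the pairwise matrix is symmetric with a zero diagonal", {
  ph <- generate_phantom(phantom_config(phi = 0.8, scale = 0.12), seed = 13)
  sel <- select_slices(ph$volume, ph$mask, 18)
  prof <- hu_profiles(ph$volume, ph$mask, build_region_map(ph$volume, ph$mask, sel))
  m <- pairwise_focal_matrix(prof)
  expect_equal(dim(m), c(9, 9))
  expect_equal(unname(diag(m)), rep(0, 9))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 200))
  # the VA-DD entry is the focal index itself
  expect_equal(
    m["ventral_apical", "dorsal_diaphragmatic"],
    focal_index(prof)$value
  )
})

test_that("homogeneous regions give a near-zero matrix", {
  ph <- generate_phantom(phantom_config(phi = 0, scale = 0.2), seed = 14)
  sel <- select_slices(ph$volume, ph$mask, 18)
  prof <- hu_profiles(ph$volume, ph$mask, build_region_map(ph$volume, ph$mask, sel))
  m <- pairwise_focal_matrix(prof)
  expect_true(all(m < 15)) # sampling noise only, small ROIs
})
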