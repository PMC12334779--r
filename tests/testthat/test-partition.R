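make_span_scan <- function(nz, lung_slices) {
  m <- array(FALSE, c(nz, 4, 4))
  m[lung_slices, 2:3, 2:3] <- TRUE
  list(
    volume = ct_volume(array(-500, c(nz, 4, 4)), spacing = c(1.5, 1, 1)),
    mask = lung_mask(m)
  )
}

test_that("slice selection spans the lung extent with even spacing", {
  s <- make_span_scan(190, 10:180)
  sel <- select_slices(s$volume, s$mask, 18)
  expect_length(sel$indices, 18)
  expect_equal(sel$indices[1], 10)
  expect_equal(sel$indices[18], 180)
  expect_true(all(diff(sel$indices) > 0))
  # near the ideal uniform grid
  expect_true(all(abs(sel$indices - seq(10, 180, length.out = 18)) <= 1))
  expect_equal(sel$slice_thickness, 1.5)

  # identity when the extent is exactly 18 slices
  s2 <- make_span_scan(30, 7:24)
  expect_equal(select_slices(s2$volume, s2$mask, 18)$indices, 7:24)

  # 19-slice extent: one interior slice skipped, endpoints kept, monotone
  s3 <- make_span_scan(25, 3:21)
  sel3 <- select_slices(s3$volume, s3$mask, 18)
  expect_length(sel3$indices, 18)
  expect_equal(range(sel3$indices), c(3, 21))
  expect_true(all(diff(sel3$indices) %in% c(1, 2)))
  expect_equal(sum(diff(sel3$indices) == 2), 1)
  expect_true(all(abs(sel3$indices - seq(3, 21, length.out = 18)) <= 1))

  expect_error(
    select_slices(make_span_scan(20, 5:15)$volume, make_span_scan(20, 5:15)$mask, 18),
    class = "focalindex_extent_error"
  )
})

test_that("craniocaudal bands split the selection into equal thirds", {
  bands <- assign_cc_bands(1:18)
  expect_equal(as.integer(table(bands$cc_band)), c(6, 6, 6))
  expect_equal(as.character(bands$cc_band[1]), "apical")
  expect_equal(as.character(bands$cc_band[18]), "diaphragmatic")
  expect_error(assign_cc_bands(18:1), class = "focalindex_input_error")
  expect_error(assign_cc_bands(1:16), class = "focalindex_partition_error")
  expect_equal(as.integer(table(assign_cc_bands(seq(2, 46, by = 4))$cc_band)), c(4, 4, 4))
})

test_that("gravitational thirds cut the per-slice lung extent into equal mm bands", {
  nz <- 18
  m <- array(FALSE, c(nz, 100, 10))
  m[, 21:80, 3:8] <- TRUE # AP rows 21..80: 60 rows
  v <- ct_volume(array(-500, c(nz, 100, 10)), spacing = c(1.5, 1, 1))
  mask <- lung_mask(m)
  sel <- select_slices(v, mask, 18)
  g <- assign_grav_bands(v, mask, sel)
  expect_equal(sort(unique(g$ap_row[g$grav_band == "ventral"])), 21:40)
  expect_equal(sort(unique(g$ap_row[g$grav_band == "medial"])), 41:60)
  expect_equal(sort(unique(g$ap_row[g$grav_band == "dorsal"])), 61:80)
  # symmetric extent: ventral and dorsal voxel counts equal
  expect_equal(sum(g$grav_band == "ventral"), sum(g$grav_band == "dorsal"))

  # single-row degenerate extent: everything ventral, still total
  m1 <- array(FALSE, c(nz, 100, 10))
  m1[, 50, 3:8] <- TRUE
  g1 <- assign_grav_bands(v, lung_mask(m1), select_slices(v, lung_mask(m1), 18))
  expect_true(all(g1$grav_band == "ventral"))
  expect_equal(nrow(g1), sum(m1))
})

test_that("the nine-region map partitions the selected in-mask voxels", {
  s <- cuboid_scan(nz = 18, rows = 5:34, cols = 4:27) # 30 AP rows: equal thirds
  sel <- select_slices(s$volume, s$mask, 18)
  rmap <- build_region_map(s$volume, s$mask, sel)
  expect_equal(nrow(rmap$counts), 9)
  expect_equal(sum(rmap$counts$n_voxels), sum(unclass(s$mask)[sel$indices, , ]))
  # uniform cuboid: all nine ROI counts equal
  expect_equal(length(unique(rmap$counts$n_voxels)), 1)
  # partition property: labels in the array cover exactly the selected in-mask voxels
  expect_equal(sum(rmap$roi > 0), sum(rmap$counts$n_voxels))
  expect_true(all(rmap$roi[unclass(s$mask) & rmap$roi > 0] %in% 1:9))

  # empty apical third: three empty ROIs and a warning
  s2 <- cuboid_scan(nz = 18, slices = 7:18, rows = 5:34)
  warns <- character(0)
  withCallingHandlers(
    rmap2 <- build_region_map(s2$volume, s2$mask, structure(
      list(indices = 1:18, slice_thickness = 1.5),
      class = "slice_selection"
    )),
    warning = function(w) {
      warns <<- c(warns, class(w)[1])
      invokeRestart("muffleWarning")
    }
  )
  expect_true("focalindex_empty_roi_warning" %in% warns)
  empty <- rmap2$counts$n_voxels == 0
  expect_equal(sum(empty), 3)
  expect_true(all(rmap2$counts$cc_band[empty] == "apical"))
})

test_that("mirroring left-right preserves counts; flipping AP swaps ventral/dorsal", {
  ph <- generate_phantom(phantom_config(phi = 0.7, scale = 0.12), seed = 5)
  v <- ph$volume
  m <- ph$mask
  sel <- select_slices(v, m, 18)
  base <- build_region_map(v, m, sel)$counts

  flip_lr <- function(a) a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
  v_lr <- ct_volume(flip_lr(v$voxels), spacing = v$spacing)
  m_lr <- lung_mask(flip_lr(array(unclass(m), dim(m))))
  lr <- build_region_map(v_lr, m_lr, select_slices(v_lr, m_lr, 18))$counts
  expect_equal(lr$n_voxels, base$n_voxels)

  # AP flip: use a mask whose AP extent (30 rows, L = 29 mm) puts no voxel
  # row exactly on a thirds boundary, where the dorsal-wards tie-break would
  # otherwise break the mirror symmetry; an off-centre lump makes the bands
  # unequal so the swap is informative
  arr <- array(FALSE, c(18, 40, 30))
  arr[, 5:34, 4:27] <- TRUE
  arr[, 8:12, 2:3] <- TRUE # extra ventral-band voxels
  vb <- ct_volume(array(-500, dim(arr)), spacing = c(1.5, 1, 1))
  mb <- lung_mask(arr)
  cnt <- build_region_map(vb, mb, select_slices(vb, mb, 18))$counts
  flip_ap <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  mb_ap <- lung_mask(flip_ap(arr))
  vb_ap <- ct_volume(flip_ap(vb$voxels), spacing = vb$spacing)
  cnt_ap <- build_region_map(vb_ap, mb_ap, select_slices(vb_ap, mb_ap, 18))$counts
  relabel <- c(ventral = "dorsal", medial = "medial", dorsal = "ventral")
  for (i in seq_len(9)) {
    j <- which(
      as.character(cnt_ap$grav_band) == relabel[[as.character(cnt$grav_band[i])]] &
        cnt_ap$cc_band == cnt$cc_band[i]
    )
    expect_equal(cnt_ap$n_voxels[j], cnt$n_voxels[i])
  }
  expect_gt(
    cnt$n_voxels[cnt$grav_band == "ventral" & cnt$cc_band == "apical"],
    cnt$n_voxels[cnt$grav_band == "dorsal" & cnt$cc_band == "apical"]
  )
})
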