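test_that("DICOM series round trip reproduces HU values and geometry", {
  set.seed(21)
  vox <- array(round(runif(6 * 16 * 14, -1000, 100)), c(6, 16, 14))
  v <- ct_volume(vox, spacing = c(2.5, 0.8, 0.9), source_id = "dcm")
  dir <- file.path(tempdir(), "dcm_rt")
  unlink(dir, recursive = TRUE)
  write_dicom_series(v, dir)
  v2 <- read_ct(dir, format = "dicom_series")
  expect_equal(v2$voxels, v$voxels)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-9)
})

test_that("rescale slope and intercept map stored values to HU", {
  # stored 524 with slope 1, intercept -1024 must read back as -500 HU
  vox <- array(-500, c(2, 4, 4))
  v <- ct_volume(vox, spacing = c(1, 1, 1))
  dir <- file.path(tempdir(), "dcm_rescale")
  unlink(dir, recursive = TRUE)
  write_dicom_series(v, dir, slope = 1, intercept = -1024)
  raw <- readBin(list.files(dir, full.names = TRUE)[1], "raw", n = 1e6)
  pix_tag <- as.raw(c(0xe0, 0x7f, 0x10, 0x00)) # (7FE0,0010) little endian
  cand <- which(raw == pix_tag[1])
  cand <- cand[cand + 3 <= length(raw) &
    raw[cand + 1] == pix_tag[2] &
    raw[cand + 2] == pix_tag[3] &
    raw[cand + 3] == pix_tag[4]]
  hit <- cand[1]
  # explicit-VR OW header is 12 bytes: tag, VR, reserved, 32-bit length
  stored <- readBin(raw[hit + 12 + 0:1], "integer", size = 2, signed = TRUE, endian = "little")
  expect_equal(stored, 524)
  expect_equal(read_ct(dir)$voxels[1, 1, 1], -500)

  # a non-trivial slope: HU = 2 * stored + (-1000)
  v2 <- ct_volume(array(-300, c(2, 3, 3)))
  dir2 <- file.path(tempdir(), "dcm_slope")
  unlink(dir2, recursive = TRUE)
  write_dicom_series(v2, dir2, slope = 2, intercept = -1000)
  expect_equal(read_ct(dir2)$voxels[2, 2, 2], -300)
})

test_that("pydicom independently confirms the DICOM encoding", {
  python <- Sys.which("python")
  expect_true(nzchar(python)) # pre-installed interpreter with pydicom
  vox <- array(seq(-1000, 100, length.out = 3 * 5 * 4), c(3, 5, 4))
  vox <- round(vox)
  v <- ct_volume(vox, spacing = c(2, 1, 1))
  dir <- file.path(tempdir(), "dcm_oracle")
  unlink(dir, recursive = TRUE)
  write_dicom_series(v, dir)
  script <- paste(
    "import pydicom, sys, glob",
    sprintf("files = sorted(glob.glob(r'%s/*.dcm'))", dir),
    "ds = pydicom.dcmread(files[0])",
    "hu = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)",
    "print(int(ds.Rows), int(ds.Columns))",
    "print(' '.join(str(int(x)) for x in hu.flatten()))",
    sep = "\n"
  )
  out <- system2(python, "-", input = script, stdout = TRUE, stderr = FALSE)
  dims <- as.integer(strsplit(out[1], " ")[[1]])
  expect_equal(dims, c(5L, 4L))
  hu <- as.numeric(strsplit(out[2], " ")[[1]])
  # pydicom returns row-major pixels of the first (most cranial) slice
  expect_equal(matrix(hu, nrow = 5, byrow = TRUE), vox[1, , ])
})

test_that("inconsistent series geometry raises a geometry error", {
  v <- ct_volume(array(0, c(3, 6, 6)), spacing = c(1, 1, 1))
  dir <- file.path(tempdir(), "dcm_geom")
  unlink(dir, recursive = TRUE)
  write_dicom_series(v, dir)
  # corrupt one slice with a different pixel spacing
  odd <- ct_volume(array(0, c(2, 6, 6)), spacing = c(1, 2, 2))
  dir_odd <- file.path(tempdir(), "dcm_geom_odd")
  unlink(dir_odd, recursive = TRUE)
  write_dicom_series(odd, dir_odd)
  file.copy(
    list.files(dir_odd, full.names = TRUE)[1],
    file.path(dir, "slice_004.dcm")
  )
  expect_error(read_ct(dir), class = "focalindex_geometry_error")
})
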