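# Minimal DICOM support for HU-calibrated CT series.
#
# Scope: uncompressed pixel data, implicit or explicit VR little endian,
# axis-aligned image orientation, one series per directory. This covers
# conventional axial CT exports; anything fancier (compressed transfer
# syntaxes, oblique gantry geometry, multiframe objects) is rejected with an
# explicit error rather than mis-read.

.dcm_uint <- function(raw, offset, n) {
  sum(as.numeric(raw[offset + seq_len(n)]) * 256^(seq_len(n) - 1))
}

.dcm_str <- function(raw, offset, n) {
  if (n == 0) return("")
  trimws(rawToChar(raw[offset + seq_len(n)][raw[offset + seq_len(n)] != as.raw(0)]))
}

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one dataset (or file meta group) returning a named list of elements
# keyed "ggggeeee" with value offsets/lengths; values decoded lazily.
.dcm_parse <- function(raw, start, end, explicit, stop_group = NULL) {
  elements <- list()
  p <- start
  while (p + 8 <= end) {
    group <- .dcm_uint(raw, p, 2)
    elem <- .dcm_uint(raw, p + 2, 2)
    if (!is.null(stop_group) && group != stop_group) break
    if (explicit) {
      vr <- rawToChar(raw[(p + 5):(p + 6)])
      if (vr %in% .LONG_VRS) {
        len <- .dcm_uint(raw, p + 8, 4)
        hdr <- 12
      } else {
        len <- .dcm_uint(raw, p + 6, 2)
        hdr <- 8
      }
    } else {
      vr <- NA_character_
      len <- .dcm_uint(raw, p + 4, 4)
      hdr <- 8
    }
    if (len == 4294967295) { # undefined length: scan for sequence delimiter
      q <- p + hdr
      repeat {
        if (q + 8 > end) {
          abort("Corrupt DICOM: unterminated undefined-length element.",
            class = "focalindex_read_error"
          )
        }
        if (.dcm_uint(raw, q, 2) == 0xFFFE && .dcm_uint(raw, q + 2, 2) == 0xE0DD) {
          break
        }
        q <- q + 2
      }
      value_len <- q - (p + hdr)
      next_p <- q + 8
    } else {
      value_len <- len
      next_p <- p + hdr + len
    }
    key <- sprintf("%04x%04x", group, elem)
    elements[[key]] <- list(offset = p + hdr, length = value_len, vr = vr)
    p <- next_p
  }
  list(elements = elements, end = p)
}

.dcm_element_str <- function(raw, els, key, default = NULL) {
  e <- els[[key]]
  if (is.null(e)) return(default)
  .dcm_str(raw, e$offset, e$length)
}

.dcm_element_us <- function(raw, els, key, default = NULL) {
  e <- els[[key]]
  if (is.null(e)) return(default)
  .dcm_uint(raw, e$offset, 2)
}

.dcm_element_ds <- function(raw, els, key, default = NULL) {
  s <- .dcm_element_str(raw, els, key)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

# Read a single DICOM file; returns header fields and the HU-rescaled slice
# matrix indexed [row, col].
.read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    abort(sprintf("'%s' is not a DICOM part-10 file.", basename(path)),
      class = "focalindex_read_error"
    )
  }
  meta <- .dcm_parse(raw, 132, length(raw), explicit = TRUE, stop_group = 0x0002)
  ts <- .dcm_element_str(raw, meta$elements, "00020010", "1.2.840.10008.1.2.1")
  explicit <- switch(ts,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    abort(sprintf("Unsupported DICOM transfer syntax '%s'.", ts),
      class = "focalindex_read_error"
    )
  )
  ds <- .dcm_parse(raw, meta$end, length(raw), explicit = explicit)
  els <- ds$elements
  rows <- .dcm_element_us(raw, els, "00280010")
  cols <- .dcm_element_us(raw, els, "00280011")
  pix <- els[["7fe00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix)) {
    abort(sprintf("'%s' lacks image dimensions or pixel data.", basename(path)),
      class = "focalindex_read_error"
    )
  }
  bits <- .dcm_element_us(raw, els, "00280100", 16)
  if (bits != 16) {
    abort("Only 16-bit DICOM pixel data is supported.",
      class = "focalindex_read_error"
    )
  }
  signed <- .dcm_element_us(raw, els, "00280103", 0) == 1
  stored <- readBin(raw[pix$offset + seq_len(2 * rows * cols)],
    "integer",
    n = rows * cols, size = 2, signed = signed, endian = "little"
  )
  slope <- .dcm_element_ds(raw, els, "00281053", 1)[1]
  intercept <- .dcm_element_ds(raw, els, "00281052", 0)[1]
  list(
    rows = rows, cols = cols,
    pixel_spacing = .dcm_element_ds(raw, els, "00280030"),
    slice_thickness = .dcm_element_ds(raw, els, "00180050", NA_real_)[1],
    ipp = .dcm_element_ds(raw, els, "00200032"),
    iop = .dcm_element_ds(raw, els, "00200037"),
    hu = matrix(slope * stored + intercept, nrow = rows, byrow = TRUE)
  )
}

# Map an axis-aligned LPS direction vector to its RAS-style letter.
.direction_letter <- function(v) {
  i <- which.max(abs(v))
  if (abs(v[i]) < 0.999 || sum(abs(v[-i])) > 1e-3) {
    abort(
      "DICOM series is not axis-aligned (oblique acquisition); cannot canonicalize.",
      class = "focalindex_orientation_error"
    )
  }
  letters <- rbind(
    c("R", "L"), # DICOM -x/+x
    c("A", "P"), # DICOM -y/+y
    c("I", "S") # DICOM -z/+z
  )
  letters[i, if (v[i] > 0) 2L else 1L]
}

#' Read a DICOM series directory as a canonical CT volume
#'
#' Slices are sorted along the slice normal, rescale slope/intercept are
#' applied to yield HU, and the volume is reoriented to the canonical
#' (cranial-caudal, ventral-dorsal, left-right) storage order. All slices must
#' share grid size, pixel spacing and orientation, and slice positions must be
#' uniformly spaced.
#'
#' @param path Directory containing the `.dcm` files of one series.
#' @param source_id Scan identifier.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(path, source_id = basename(path)) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE, ignore.case = TRUE)
  if (!length(files)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
  }
  if (length(files) < 2) {
    abort(sprintf("No DICOM series (>= 2 slices) found in '%s'.", path),
      class = "focalindex_read_error"
    )
  }
  slices <- lapply(files, .read_dicom_file)
  ref <- slices[[1]]
  same_grid <- vapply(slices, function(s) {
    s$rows == ref$rows && s$cols == ref$cols &&
      isTRUE(all.equal(s$pixel_spacing, ref$pixel_spacing, tolerance = 1e-6)) &&
      isTRUE(all.equal(s$iop, ref$iop, tolerance = 1e-6))
  }, logical(1))
  if (!all(same_grid)) {
    abort("DICOM slices disagree on grid size, spacing or orientation.",
      class = "focalindex_geometry_error"
    )
  }
  if (is.null(ref$iop) || length(ref$iop) != 6 || is.null(ref$ipp)) {
    abort("DICOM series lacks orientation/position metadata.",
      class = "focalindex_orientation_error"
    )
  }
  row_dir <- ref$iop[1:3]
  col_dir <- ref$iop[4:6]
  normal <- c(
    row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
    row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
    row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1]
  )
  proj <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(proj)
  steps <- diff(proj[ord])
  if (any(steps <= 0) || (max(steps) - min(steps)) > 1e-3 * mean(steps)) {
    abort("DICOM slice positions are duplicated or non-uniformly spaced.",
      class = "focalindex_geometry_error"
    )
  }
  vol <- array(0, dim = c(length(slices), ref$rows, ref$cols))
  for (i in seq_along(ord)) vol[i, , ] <- slices[[ord[i]]]$hu
  spacing <- c(mean(steps), ref$pixel_spacing[1], ref$pixel_spacing[2])
  axis_letters <- c(
    .direction_letter(normal), # slice index axis
    .direction_letter(col_dir), # row index axis
    .direction_letter(row_dir) # column index axis
  )
  canon <- .canonicalize_array(vol, spacing, axis_letters)
  ct_volume(canon$voxels, spacing = canon$spacing, source_id = source_id)
}

# Reorder/flip an array whose axes point along `letters` (RAS letters) into
# the canonical (I, P, R) order.
.canonicalize_array <- function(arr, spacing, letters) {
  target <- c("I", "P", "R")
  opposite <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")
  perm <- integer(3)
  flip <- logical(3)
  for (k in 1:3) {
    hit <- which(letters == target[k])
    if (length(hit) == 1) {
      perm[k] <- hit
    } else {
      hit <- which(letters == opposite[[target[k]]])
      if (length(hit) != 1) {
        abort("Degenerate axis labels; cannot canonicalize.",
          class = "focalindex_orientation_error"
        )
      }
      perm[k] <- hit
      flip[k] <- TRUE
    }
  }
  out <- aperm(arr, perm)
  idx <- lapply(1:3, function(k) {
    if (flip[k]) rev(seq_len(dim(out)[k])) else seq_len(dim(out)[k])
  })
  list(voxels = out[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], spacing = spacing[perm])
}

# ---- writer (used for fixtures and round-trip validation) -------------------

.dcm_pad <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2 == 1) c(x, pad) else x
}

.dcm_el <- function(group, elem, vr, value_raw) {
  value_raw <- .dcm_pad(value_raw, if (vr %in% c("UI", "OB")) as.raw(0) else as.raw(0x20))
  tag <- writeBin(as.integer(c(group, elem)), raw(), size = 2, endian = "little")
  header <- if (vr %in% .LONG_VRS) {
    c(
      tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little")
    )
  } else {
    c(
      tag, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little")
    )
  }
  c(header, value_raw)
}

.dcm_el_str <- function(group, elem, vr, s) .dcm_el(group, elem, vr, charToRaw(s))
.dcm_el_us <- function(group, elem, v) {
  .dcm_el(group, elem, "US", writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

#' Write a canonical CT volume as a DICOM series
#'
#' Emits one explicit-VR little-endian CT file per canonical slice with
#' standard axial geometry, 16-bit signed storage and the given rescale
#' parameters (HU = slope x stored + intercept). Intended for fixtures and
#' interoperability checks, not clinical archiving.
#'
#' @param volume A [ct_volume()].
#' @param dir Output directory (created if needed).
#' @param slope,intercept Rescale parameters used to encode stored values.
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir, slope = 1, intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(volume$voxels)
  sp <- volume$spacing
  series_uid <- paste0("1.2.826.0.1.3680043.9999.", paste(dims, collapse = "."))
  for (s in seq_len(dims[1])) {
    # canonical slice axis points Inferior: world z decreases with slice index
    ipp <- c(0, 0, -(s - 1) * sp[1])
    stored <- round((volume$voxels[s, , ] - intercept) / slope)
    if (any(stored < -32768 | stored > 32767)) {
      abort("Stored values overflow int16 for the chosen rescale parameters.",
        class = "focalindex_input_error"
      )
    }
    # row-major pixel order: rows are the ventral-dorsal axis (axis 2)
    pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
    dataset <- c(
      .dcm_el_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_el_str(0x0008, 0x0018, "UI", paste0(series_uid, ".", s)),
      .dcm_el_str(0x0008, 0x0060, "CS", "CT"),
      .dcm_el_str(0x0018, 0x0050, "DS", format(sp[1])),
      .dcm_el_str(0x0020, 0x000E, "UI", series_uid),
      .dcm_el_str(0x0020, 0x0013, "IS", as.character(s)),
      .dcm_el_str(0x0020, 0x0032, "DS", paste(format(ipp), collapse = "\\")),
      # rows run ventral->dorsal (+y, P); columns run left->right (-x, R)
      .dcm_el_str(0x0020, 0x0037, "DS", "-1\\0\\0\\0\\1\\0"),
      .dcm_el_us(0x0028, 0x0002, 1),
      .dcm_el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_el_us(0x0028, 0x0010, dims[2]),
      .dcm_el_us(0x0028, 0x0011, dims[3]),
      .dcm_el_str(0x0028, 0x0030, "DS", paste(format(c(sp[2], sp[3])), collapse = "\\")),
      .dcm_el_us(0x0028, 0x0100, 16),
      .dcm_el_us(0x0028, 0x0101, 16),
      .dcm_el_us(0x0028, 0x0102, 15),
      .dcm_el_us(0x0028, 0x0103, 1),
      .dcm_el_str(0x0028, 0x1052, "DS", format(intercept)),
      .dcm_el_str(0x0028, 0x1053, "DS", format(slope)),
      .dcm_el(0x7FE0, 0x0010, "OW", pix)
    )
    meta_body <- c(
      .dcm_el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcm_el_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_el_str(0x0002, 0x0003, "UI", paste0(series_uid, ".", s)),
      .dcm_el_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    meta <- c(
      .dcm_el(0x0002, 0x0000, "UL",
        writeBin(length(meta_body), raw(), size = 4, endian = "little")
      ),
      meta_body
    )
    con <- file(file.path(dir, sprintf("slice_%03d.dcm", s)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
    close(con)
  }
  invisible(dir)
}
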