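# Small in-code fixtures shared across test files.

iso_geom <- function(shape, spacing = 0.5) {
  voxelGeometry(shape, spacing = rep(spacing, 3))
}

mask_from <- function(values, spacing = c(0.5, 0.5, 0.5)) {
  binaryMask(values, voxelGeometry(dim(values), spacing = spacing))
}

vol_from <- function(values, spacing = c(0.5, 0.5, 0.5)) {
  huVolume(values, voxelGeometry(dim(values), spacing = spacing))
}

# A small, fast phantom used where the default would be needlessly heavy.
small_phantom_spec <- function(...) {
  phantomSpec(cavity_semi_axes_mm = c(12, 12, 30), ...)
}

# Square landmark ring of side `side` in the z = z0 plane (ordered loop).
square_ring <- function(side = 1, z0 = 0, center = c(0, 0)) {
  h <- side / 2
  landmarkSet(rbind(
    c(center[1] - h, center[2] - h, z0),
    c(center[1] + h, center[2] - h, z0),
    c(center[1] + h, center[2] + h, z0),
    c(center[1] - h, center[2] + h, z0)
  ))
}

# Minimal explicit-VR little-endian DICOM slice writer for reader tests.
write_test_dicom <- function(path, stored, rows, cols,
                             ipp = c(0, 0, 0),
                             iop = c(1, 0, 0, 0, 1, 0),
                             pixel_spacing = c(0.5, 0.5),
                             slope = 1, intercept = 0,
                             series_uid = "1.2.826.0.1.999999.1",
                             pixel_rep = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  pad <- function(s) {
    b <- charToRaw(s)
    if (length(b) %% 2L) c(b, as.raw(0)) else b
  }
  elem <- function(g, e, vr, bytes) {
    writeBin(as.raw(c(bitwAnd(g, 255L), bitwShiftR(g, 8L),
                      bitwAnd(e, 255L), bitwShiftR(e, 8L))), con)
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      writeBin(as.raw(c(0, 0)), con)
      writeBin(length(bytes), con, size = 4L, endian = "little")
    } else {
      writeBin(length(bytes), con, size = 2L, endian = "little")
    }
    writeBin(bytes, con)
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                             endian = "little")
  ds <- function(...) pad(paste(sprintf("%g", c(...)), collapse = "\\"))
  elem(0x0002L, 0x0010L, "UI", pad("1.2.840.10008.1.2.1"))
  elem(0x0020L, 0x000eL, "UI", pad(series_uid))
  elem(0x0020L, 0x0032L, "DS", ds(ipp))
  elem(0x0020L, 0x0037L, "DS", ds(iop))
  elem(0x0028L, 0x0010L, "US", us(rows))
  elem(0x0028L, 0x0011L, "US", us(cols))
  elem(0x0028L, 0x0030L, "DS", ds(pixel_spacing))
  elem(0x0028L, 0x0100L, "US", us(16L))
  elem(0x0028L, 0x0103L, "US", us(pixel_rep))
  elem(0x0028L, 0x1052L, "DS", ds(intercept))
  elem(0x0028L, 0x1053L, "DS", ds(slope))
  px <- writeBin(as.integer(stored), raw(), size = 2L, endian = "little")
  elem(0x7fe0L, 0x0010L, "OW", px)
  invisible(path)
}
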