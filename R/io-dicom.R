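#' @include utils.R io.R
NULL

# Minimal DICOM reader: explicit-VR little-endian, uncompressed single-frame
# CT slices. Scoped to the tags a CT series needs (geometry, rescale,
# pixels); anything fancier (implicit VR, undefined lengths, compressed
# transfer syntaxes) is rejected with a descriptive error.

dicom_u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
dicom_u32 <- function(raw, at) {
  dicom_u16(raw, at) + 65536 * dicom_u16(raw, at + 2L)
}

parse_dicom_slice <- function(path) {
  n <- file.size(path)
  raw <- readBin(path, "raw", n)
  pos <- 1L
  if (n > 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  while (pos + 7L <= n) {
    g <- dicom_u16(raw, pos)
    e <- dicom_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      orb_stop("orbvol_io_error",
               "'%s': only explicit-VR little-endian DICOM is supported",
               path)
    if (vr %in% long_vrs) {
      len <- dicom_u32(raw, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- dicom_u16(raw, pos + 6L)
      vstart <- pos + 8L
    }
    if (len == 4294967295)
      orb_stop("orbvol_io_error",
               "'%s': undefined-length DICOM elements are not supported",
               path)
    key <- sprintf("%04x,%04x", g, e)
    tags[[key]] <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    pos <- vstart + len
    if (g == 0x7fe0L && e == 0x0010L) break
  }
  tags
}

dicom_string <- function(tags, key, default = NULL) {
  if (is.null(tags[[key]])) return(default)
  trimws(rawToChar(tags[[key]]))
}
dicom_numbers <- function(tags, key, default = NULL) {
  s <- dicom_string(tags, key)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dicom_us <- function(tags, key, default = NULL) {
  if (is.null(tags[[key]])) return(default)
  dicom_u16(tags[[key]], 1L)
}

read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files))
    orb_stop("orbvol_io_error", "'%s': empty DICOM directory", dir)
  slices <- lapply(files, parse_dicom_slice)

  uid <- unique(vapply(slices, function(t)
    dicom_string(t, "0020,000e", ""), ""))
  if (length(uid) > 1L)
    orb_stop("orbvol_io_error",
             "'%s': mixed series (multiple SeriesInstanceUIDs) in one directory",
             dir)

  first <- slices[[1L]]
  rows <- dicom_us(first, "0028,0010")
  cols <- dicom_us(first, "0028,0011")
  ps <- dicom_numbers(first, "0028,0030")  # (row spacing, column spacing)
  iop <- dicom_numbers(first, "0020,0037")
  if (is.null(rows) || is.null(cols) || is.null(ps) || is.null(iop))
    orb_stop("orbvol_io_error",
             "'%s': missing Rows/Columns/PixelSpacing/ImageOrientationPatient",
             files[1])
  row_dir <- iop[1:3]  # direction of increasing column index
  col_dir <- iop[4:6]  # direction of increasing row index
  normal <- cross3(row_dir, col_dir)

  for (t in slices) {
    iop_i <- dicom_numbers(t, "0020,0037")
    if (max(abs(iop_i - iop)) > 1e-6)
      orb_stop("orbvol_io_error",
               "'%s': inconsistent slice orientations in series", dir)
  }

  proj <- vapply(slices, function(t)
    sum(dicom_numbers(t, "0020,0032") * normal), 0.0)
  ord <- order(proj)
  slices <- slices[ord]
  proj <- proj[ord]

  if (length(slices) > 1L) {
    gaps <- diff(proj)
    if (any(gaps <= 0))
      orb_stop("orbvol_io_error", "'%s': duplicate slice positions", dir)
    if (max(gaps) - min(gaps) > 1e-3)
      orb_stop("orbvol_io_error",
               "'%s': non-uniform slice spacing beyond 1e-3 mm tolerance",
               dir)
    dz <- mean(gaps)
  } else {
    dz <- dicom_numbers(first, "0018,0050", 1.0)[1]  # SliceThickness
  }

  vals <- vapply(slices, function(t) {
    bits <- dicom_us(t, "0028,0100", 16L)
    if (bits != 16L)
      orb_stop("orbvol_io_error", "only 16-bit DICOM pixel data supported")
    signed <- identical(dicom_us(t, "0028,0103", 0L), 1L)
    px <- t[["7fe0,0010"]]
    if (is.null(px))
      orb_stop("orbvol_io_error", "DICOM slice without PixelData")
    stored <- readBin(px, "integer", n = rows * cols, size = 2L,
                      signed = signed, endian = "little")
    slope <- dicom_numbers(t, "0028,1053", 1.0)[1]
    inter <- dicom_numbers(t, "0028,1052", 0.0)[1]
    slope * stored + inter
  }, numeric(rows * cols))

  geom <- voxelGeometry(c(cols, rows, length(slices)),
                        spacing = c(ps[2], ps[1], dz),
                        origin = dicom_numbers(slices[[1L]], "0020,0032"),
                        directions = cbind(row_dir, col_dir, normal))
  huVolume(array(as.numeric(vals), c(cols, rows, length(slices))), geom)
}
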