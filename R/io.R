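#' @include AllClasses.R utils.R
NULL

# NIfTI affines address RAS world space; the package works in the DICOM
# patient frame (LPS). Conversion negates the first two world axes.
ras_to_lps <- diag(c(-1, -1, 1, 1))

geom_to_affine_lps <- function(geom) {
  rbind(cbind(geom@directions %*% diag(geom@spacing), geom@origin),
        c(0, 0, 0, 1))
}

affine_lps_to_geom <- function(A, shape, tol = 1e-6) {
  M <- A[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0))
    orb_stop("orbvol_io_error", "degenerate affine: zero-length axis")
  D <- sweep(M, 2L, spacing, "/")
  if (max(abs(crossprod(D) - diag(3))) > tol)
    orb_stop("orbvol_io_error",
             "non-orthogonal image affine is not supported")
  voxelGeometry(shape, spacing = spacing, origin = A[1:3, 4], directions = D)
}

read_nifti_geom <- function(path) {
  img <- RNifti::readNifti(path)
  A_ras <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  A_lps <- ras_to_lps %*% A_ras[1:4, 1:4]
  d <- dim(img)
  if (length(d) != 3L)
    orb_stop("orbvol_io_error", "'%s': expected a 3-D NIfTI volume", path)
  list(values = array(as.numeric(img), d),
       geometry = affine_lps_to_geom(A_lps, d))
}

write_nifti_geom <- function(values, geom, path, datatype) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- geom@spacing
  A_ras <- ras_to_lps %*% geom_to_affine_lps(geom)
  img <- RNifti::`sform<-`(img, structure(A_ras, code = 2L))
  img <- RNifti::`qform<-`(img, structure(A_ras, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a CT volume as Hounsfield units
#'
#' Reads either a NIfTI file or a directory holding one DICOM CT series.
#' DICOM slices are sorted by position along the slice normal, rescale
#' slope/intercept are applied to produce HU, and slice spacing must be
#' uniform within 1e-3 mm. NIfTI intensities are taken as already in HU
#' unless the file carries scaling metadata (applied by the reader). World
#' coordinates are the DICOM patient frame (LPS); NIfTI RAS affines are
#' converted on read.
#'
#' @param path NIfTI file or DICOM series directory.
#' @return An \linkS4class{HUVolume}.
#' @export
readCT <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path))
    orb_stop("orbvol_io_error", "'%s' does not exist", path)
  nf <- read_nifti_geom(path)
  huVolume(nf$values, nf$geometry)
}

#' Read and write binary masks as NIfTI
#'
#' Masks are stored as uint8 NIfTI volumes with values {0, 1} and the full
#' geometry in the affine; the round trip is lossless. Uncompressed
#' \code{.nii} output is byte-deterministic for identical inputs.
#'
#' @param m a \linkS4class{BinaryMask}.
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{readMask} returns a \linkS4class{BinaryMask};
#'   \code{writeMask} returns the path invisibly.
#' @export
writeMask <- function(m, path) {
  write_nifti_geom(array(as.integer(m@values), dim(m@values)), m@geometry,
                   path, datatype = "uint8")
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (!file.exists(path))
    orb_stop("orbvol_io_error", "'%s' does not exist", path)
  nf <- read_nifti_geom(path)
  new("BinaryMask", geometry = nf$geometry,
      values = array(nf$values != 0, dim(nf$values)))
}

#' Write an HU volume as NIfTI
#' @param vol an \linkS4class{HUVolume}.
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeCT <- function(vol, path) {
  write_nifti_geom(vol@values, vol@geometry, path, datatype = "float32")
}

#' Read and write rim landmarks
#'
#' CSV files use the header \code{label,x,y,z} (mm, LPS); JSON files hold a
#' list of \code{[x, y, z]} triples (optionally an object with a
#' \code{points} member and a \code{label}). Format is chosen by file
#' extension.
#'
#' @param path landmark file (.csv or .json).
#' @return \code{readLandmarks} returns a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path))
    orb_stop("orbvol_io_error", "'%s' does not exist", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.list(js) && !is.null(js$points))
      return(landmarkSet(as.matrix(js$points),
                         label = if (!is.null(js$label)) js$label else ""))
    return(landmarkSet(as.matrix(js)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    orb_stop("orbvol_io_error",
             "'%s': landmark CSV needs columns label,x,y,z", path)
  lab <- if ("label" %in% names(df)) paste(unique(df$label), collapse = ",")
         else ""
  landmarkSet(as.matrix(df[, need]), label = lab)
}

#' @rdname readLandmarks
#' @param lm a \linkS4class{LandmarkSet} to write (CSV).
#' @export
writeLandmarks <- function(lm, path) {
  df <- data.frame(label = rep(lm@label, nrow(lm@points)),
                   x = lm@points[, 1], y = lm@points[, 2],
                   z = lm@points[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a fan surface as binary STL
#'
#' For inspection in mesh viewers; triangles carry their anterior-oriented
#' normals.
#'
#' @param s a \linkS4class{FanSurface}.
#' @param path output .stl path.
#' @return The path, invisibly.
#' @export
writeSTL <- function(s, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "orbvol fan surface"))[1:80]
  writeBin(header, con)
  tri <- s@triangles
  writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
  V <- s@vertices
  for (i in seq_len(nrow(tri))) {
    p1 <- V[tri[i, 1], ]; p2 <- V[tri[i, 2], ]; p3 <- V[tri[i, 3], ]
    nrm <- cross3(p2 - p1, p3 - p1)
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm <- nrm / len
    writeBin(as.numeric(c(nrm, p1, p2, p3)), con, size = 4,
             endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Export a distance map as CSV
#'
#' One row per test-boundary point: \code{x,y,z,signed_mm} (world mm, LPS).
#'
#' @param dm a \linkS4class{DistanceMap}.
#' @param path output .csv path.
#' @return The path, invisibly.
#' @export
writeDistanceCsv <- function(dm, path) {
  df <- data.frame(x = dm@points[, 1], y = dm@points[, 2],
                   z = dm@points[, 3], signed_mm = dm@signed_distances)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Deterministic JSON writer: named lists, unboxed scalars, full precision.
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

report_list <- function(x) {
  if (methods::is(x, "AgreementReport")) {
    return(list(
      volume_test_cc = x@volume_test_cc,
      volume_ref_cc = x@volume_ref_cc,
      mean_diff_cc = x@mean_diff_cc,
      dice = x@dice,
      distance = x@distance_map@summary,
      t_statistic = x@t_statistic,
      p_value = x@p_value
    ))
  }
  if (methods::is(x, "OrbitalVolumeResult")) {
    cfg <- x@params_echo@mask_config
    return(list(
      volume_cc = x@volume_cc,
      stage_volumes_cc = as.list(x@stage_volumes_cc),
      params = list(
        bone_threshold_hu = cfg@bone_threshold_hu,
        air_threshold_hu = cfg@air_threshold_hu,
        connectivity = cfg@connectivity,
        closing_radius_mm = cfg@closing_radius_mm,
        seed_depth_mm = x@params_echo@seed_depth_mm,
        posterior_extent_mm = x@params_echo@posterior_extent_mm,
        radial_margin_mm = x@params_echo@radial_margin_mm,
        dilate_mm = x@params_echo@dilate_mm,
        anterior_hint = x@params_echo@anterior_hint
      ),
      log = x@log
    ))
  }
  if (methods::is(x, "ICCResult")) {
    return(list(
      icc = x@icc, ci_low = x@ci_low, ci_high = x@ci_high,
      model = x@model_label, n_subjects = x@n_subjects,
      n_raters = x@n_raters, mean_squares = as.list(x@mean_squares)
    ))
  }
  orb_stop("orbvol_io_error", "no JSON report defined for class %s",
           class(x)[1])
}
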