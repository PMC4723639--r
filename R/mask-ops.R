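#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' @describeIn maskVolume voxel count times voxel volume, in cc.
#' @export
setMethod("maskVolume", "BinaryMask", function(m) {
  sum(m@values) * prod(m@geometry@spacing) / 1000
})

#' @describeIn voxelCount number of TRUE voxels.
#' @export
setMethod("voxelCount", "BinaryMask", function(m) sum(m@values))

#' @describeIn geometry geometry of a mask.
#' @export
setMethod("geometry", "BinaryMask", function(x) x@geometry)

#' @describeIn geometry geometry of an HU volume.
#' @export
setMethod("geometry", "HUVolume", function(x) x@geometry)

#' Hounsfield threshold mask
#'
#' Selects voxels by inclusive HU bounds: a voxel is selected iff
#' \code{value >= lo} (when \code{lo} is given) and \code{value <= hi} (when
#' \code{hi} is given). The bone mask of the semi-automatic refinement is
#' \code{thresholdMask(vol, lo = +400)} ("+400 HU or more"); the air mask is
#' \code{thresholdMask(vol, hi = -600)} ("-600 HU or less").
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param lo lower HU bound (inclusive), or NULL.
#' @param hi upper HU bound (inclusive), or NULL.
#' @return A \linkS4class{BinaryMask} with the volume's geometry.
#' @export
thresholdMask <- function(vol, lo = NULL, hi = NULL) {
  if (is.null(lo) && is.null(hi))
    orb_stop("orbvol_threshold_error",
             "at least one of lo/hi must be given")
  if (!is.null(lo) && !is.null(hi) && lo > hi)
    orb_stop("orbvol_threshold_error",
             "invalid thresholds: lo (%g) exceeds hi (%g)", lo, hi)
  v <- vol@values
  sel <- array(TRUE, dim = dim(v))
  if (!is.null(lo)) sel <- sel & (v >= lo)
  if (!is.null(hi)) sel <- sel & (v <= hi)
  new("BinaryMask", geometry = vol@geometry, values = sel)
}

#' Boolean mask algebra
#'
#' Voxelwise set operations on masks sharing one geometry:
#' \code{maskSubtract(a, b)} keeps voxels of \code{a} not in \code{b}
#' (the "created and subtracted" step of the semi-automatic method),
#' \code{maskUnion} is OR, \code{maskIntersect} is AND.
#'
#' @param a,b \linkS4class{BinaryMask}s with identical geometry.
#' @return A \linkS4class{BinaryMask}.
#' @export
maskSubtract <- function(a, b) {
  check_same_geometry(a, b)
  new("BinaryMask", geometry = a@geometry, values = a@values & !b@values)
}

#' @rdname maskSubtract
#' @export
maskUnion <- function(a, b) {
  check_same_geometry(a, b)
  new("BinaryMask", geometry = a@geometry, values = a@values | b@values)
}

#' @rdname maskSubtract
#' @export
maskIntersect <- function(a, b) {
  check_same_geometry(a, b)
  new("BinaryMask", geometry = a@geometry, values = a@values & b@values)
}

# Integer component labels (0 = background) with deterministic ordering:
# labels increase with the first column-major voxel of each component.
label_components <- function(m, connectivity = 26L) {
  lab <- cpp_label_components(as.logical(m@values), dim(m@values),
                              as.integer(connectivity))
  array(lab, dim = dim(m@values))
}

#' Largest connected component
#'
#' Keeps the largest connected component by voxel count; removes
#' disconnected debris left by mask subtraction. Ties are broken
#' deterministically in favour of the component containing the smallest
#' voxel index in column-major order. An empty mask yields an empty mask.
#'
#' @param m a \linkS4class{BinaryMask}.
#' @param connectivity 6, 18 or 26 (default 26, tolerant of staircase
#'   boundaries at 0.5 mm voxels).
#' @return A \linkS4class{BinaryMask}.
#' @export
largestComponent <- function(m, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    orb_stop("orbvol_threshold_error", "connectivity must be 6, 18 or 26")
  if (!any(m@values)) return(m)
  lab <- label_components(m, connectivity)
  counts <- tabulate(lab[lab > 0L])
  best <- which(counts == max(counts))[1L]  # ties: smallest label wins
  new("BinaryMask", geometry = m@geometry, values = lab == best)
}

# Euclidean dilation/erosion with a physical mm-ball element: a voxel is in
# the dilation iff its centre lies within radius_mm of some mask voxel
# centre (anisotropic spacing honoured via the distance transform).
mask_dilate <- function(m, radius_mm) {
  if (radius_mm <= 0) return(m)
  if (!any(m@values)) return(m)
  d2 <- cpp_edt_sq(as.logical(m@values), dim(m@values), m@geometry@spacing)
  new("BinaryMask", geometry = m@geometry,
      values = array(d2 <= radius_mm^2 + 1e-9, dim = dim(m@values)))
}

mask_erode <- function(m, radius_mm) {
  if (radius_mm <= 0) return(m)
  if (all(m@values)) return(m)
  inv <- new("BinaryMask", geometry = m@geometry, values = !m@values)
  dil <- mask_dilate(inv, radius_mm)
  new("BinaryMask", geometry = m@geometry, values = !dil@values)
}

#' Morphological closing with a physical ball element
#'
#' Dilation followed by erosion with a Euclidean ball of \code{radius_mm}
#' millimetres (converted per axis through the voxel spacing, so behaviour
#' is spacing-invariant). Closing is extensive (result contains the input)
#' and idempotent; it spans thin-wall gaps and fissure-like holes narrower
#' than the ball, which is what seals the orbital wall before region
#' growing.
#'
#' @param m a \linkS4class{BinaryMask}.
#' @param radius_mm ball radius in mm; 0 is the identity.
#' @return A \linkS4class{BinaryMask} containing \code{m}.
#' @export
morphologicalClose <- function(m, radius_mm) {
  if (radius_mm < 0)
    orb_stop("orbvol_threshold_error", "radius_mm must be non-negative")
  if (radius_mm == 0) return(m)
  mask_erode(mask_dilate(m, radius_mm), radius_mm)
}

#' @describeIn centroid mean of an n x 3 point matrix.
#' @export
setMethod("centroid", "matrix", function(x) {
  if (nrow(x) < 1L)
    orb_stop("orbvol_degenerate_error", "centroid of an empty point set")
  colMeans(x)
})

#' @describeIn centroid centre of gravity of the rim landmarks.
#' @export
setMethod("centroid", "LandmarkSet", function(x) colMeans(x@points))
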