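#' @include AllClasses.R
NULL

#' Volume of a mask in cc
#'
#' \code{voxel_count * prod(spacing) / 1000}, with cc defined exactly as
#' cm^3 (1 cc = 1000 mm^3).
#'
#' @param m a \linkS4class{BinaryMask}.
#' @return Volume in cc.
#' @export
setGeneric("maskVolume", function(m) standardGeneric("maskVolume"))

#' Number of selected voxels
#' @param m a \linkS4class{BinaryMask}.
#' @return Integer voxel count.
#' @export
setGeneric("voxelCount", function(m) standardGeneric("voxelCount"))

#' Grid geometry accessor
#' @param x an object with a voxel geometry (volume or mask).
#' @return The \linkS4class{VoxelGeometry}.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' Arithmetic centroid (centre of gravity)
#'
#' Component-wise arithmetic mean of a point set; for a
#' \linkS4class{LandmarkSet} this is the centre of gravity of the rim
#' landmarks through which the anterior fan surface passes.
#'
#' @param x a \linkS4class{LandmarkSet} or an n x 3 point matrix.
#' @return numeric(3) world point.
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))
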