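#' @import methods
NULL

#' Voxel grid geometry
#'
#' Describes how a 3-D voxel grid sits in world space: grid shape, physical
#' spacing in millimetres, world position (mm, LPS convention) of the centre
#' of voxel (0,0,0), and an orthonormal direction matrix whose columns map
#' voxel axes to world axes. The world coordinate of the centre of voxel
#' (i,j,k) (zero-based) is \code{origin + directions \%*\% (c(i,j,k) * spacing)}.
#'
#' @slot shape integer(3), voxels per axis.
#' @slot spacing numeric(3), mm per voxel per axis; all positive.
#' @slot origin numeric(3), world mm of the centre of voxel (0,0,0).
#' @slot directions 3x3 orthonormal matrix, columns are world directions of
#'   the voxel axes.
#' @aliases VoxelGeometry
#' @exportClass VoxelGeometry
setClass("VoxelGeometry",
  slots = c(
    shape = "integer",
    spacing = "numeric",
    origin = "numeric",
    directions = "matrix"
  )
)

setValidity("VoxelGeometry", function(object) {
  msgs <- character()
  if (length(object@shape) != 3L || any(is.na(object@shape)) ||
      any(object@shape < 1L))
    msgs <- c(msgs, "shape must be 3 positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite numbers")
  D <- object@directions
  if (!is.numeric(D) || !identical(dim(D), c(3L, 3L))) {
    msgs <- c(msgs, "directions must be a numeric 3x3 matrix")
  } else if (max(abs(crossprod(D) - diag(3))) > 1e-6) {
    msgs <- c(msgs, "direction vectors must be orthonormal (tolerance 1e-6)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a VoxelGeometry
#'
#' @param shape integer(3) voxels per axis.
#' @param spacing numeric(3) mm per voxel (default 0.5 mm isotropic, the
#'   acquisition-protocol slice geometry used throughout).
#' @param origin world mm of the centre of voxel (0,0,0). The default
#'   \code{spacing / 2} places voxel centres at \code{(i + 0.5) * spacing}.
#' @param directions 3x3 orthonormal direction matrix (default identity =
#'   grid axes aligned with LPS world axes).
#' @return A \linkS4class{VoxelGeometry}.
#' @export
voxelGeometry <- function(shape, spacing = c(0.5, 0.5, 0.5),
                          origin = spacing / 2, directions = diag(3)) {
  new("VoxelGeometry", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin), directions = directions)
}

#' CT volume in Hounsfield units
#'
#' A 3-D scalar grid of Hounsfield units together with its
#' \linkS4class{VoxelGeometry}.
#'
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot values 3-D numeric array matching \code{geometry@shape}.
#' @aliases HUVolume
#' @exportClass HUVolume
setClass("HUVolume",
  slots = c(geometry = "VoxelGeometry", values = "array")
)

setValidity("HUVolume", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), as.integer(object@geometry@shape)))
    msgs <- c(msgs, "values array shape must equal geometry shape")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "HU values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an HUVolume
#'
#' Values outside the plausible CT range [-1100, +3100] HU trigger a warning
#' (not an error), as a data-quality check.
#'
#' @param values 3-D numeric array of Hounsfield units.
#' @param geometry a \linkS4class{VoxelGeometry}; defaults to 0.5 mm
#'   isotropic spacing over the array's dimensions.
#' @return An \linkS4class{HUVolume}.
#' @export
huVolume <- function(values, geometry = voxelGeometry(dim(values))) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (any(values < -1100 | values > 3100))
    warning("HU values outside the plausible CT range [-1100, 3100]",
            call. = FALSE)
  new("HUVolume", geometry = geometry, values = values)
}

#' Binary segmentation mask
#'
#' A 3-D logical grid sharing an \linkS4class{HUVolume}'s geometry; the unit
#' of every segmentation in the package. Volumes are reported in cc
#' (1 cc = 1 cm^3 = 1000 mm^3), see \code{\link{maskVolume}}.
#'
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot values 3-D logical array matching \code{geometry@shape}.
#' @aliases BinaryMask
#' @exportClass BinaryMask
setClass("BinaryMask",
  slots = c(geometry = "VoxelGeometry", values = "array")
)

setValidity("BinaryMask", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), as.integer(object@geometry@shape)))
    msgs <- c(msgs, "values array shape must equal geometry shape")
  if (!is.logical(object@values) || any(is.na(object@values)))
    msgs <- c(msgs, "mask values must be logical and non-missing")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BinaryMask
#'
#' @param values 3-D logical (or coercible) array.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @return A \linkS4class{BinaryMask}.
#' @export
binaryMask <- function(values, geometry = voxelGeometry(dim(values))) {
  values <- as.array(values)
  storage.mode(values) <- "logical"
  new("BinaryMask", geometry = geometry, values = values)
}

#' Hounsfield threshold and morphology configuration
#'
#' Holds the HU thresholds of the semi-automatic refinement -- a bone mask at
#' +400 HU or more and an air mask at -600 HU or less -- together with the
#' connectivity used for component analysis and the physical radius of the
#' morphological closing that seals thin-wall gaps.
#'
#' @slot bone_threshold_hu bone threshold, default +400 HU (inclusive).
#' @slot air_threshold_hu air threshold, default -600 HU (inclusive).
#' @slot connectivity 6, 18 or 26 (default 26).
#' @slot closing_radius_mm radius in mm of the closing ball, default 2.
#' @aliases MaskConfig
#' @exportClass MaskConfig
setClass("MaskConfig",
  slots = c(
    bone_threshold_hu = "numeric",
    air_threshold_hu = "numeric",
    connectivity = "integer",
    closing_radius_mm = "numeric"
  )
)

setValidity("MaskConfig", function(object) {
  msgs <- character()
  if (object@bone_threshold_hu <= object@air_threshold_hu)
    msgs <- c(msgs, "bone_threshold_hu must exceed air_threshold_hu")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msgs <- c(msgs, "connectivity must be 6, 18 or 26")
  if (object@closing_radius_mm < 0)
    msgs <- c(msgs, "closing_radius_mm must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MaskConfig
#'
#' @param bone_threshold_hu bone threshold in HU (default +400).
#' @param air_threshold_hu air threshold in HU (default -600).
#' @param connectivity voxel connectivity for component analysis (default 26).
#' @param closing_radius_mm physical closing radius in mm (default 2).
#' @return A \linkS4class{MaskConfig}.
#' @export
maskConfig <- function(bone_threshold_hu = 400, air_threshold_hu = -600,
                       connectivity = 26L, closing_radius_mm = 2) {
  new("MaskConfig", bone_threshold_hu = as.numeric(bone_threshold_hu),
      air_threshold_hu = as.numeric(air_threshold_hu),
      connectivity = as.integer(connectivity),
      closing_radius_mm = as.numeric(closing_radius_mm))
}

#' Ordered orbital-rim landmarks
#'
#' An ordered ring of world-coordinate points (mm, LPS) traced along the
#' orbital rim, roughly 0.5--1 cm apart, as a single closed loop. The ring is
#' validated: at least 4 points, consecutive points more than 0.1 mm apart,
#' and no self-crossing when projected on the ring's best-fit plane.
#'
#' @slot points n x 3 numeric matrix of world coordinates in mm.
#' @slot label free-text label (e.g. the side).
#' @aliases LandmarkSet
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  slots = c(points = "matrix", label = "character")
)

setValidity("LandmarkSet", function(object) {
  P <- object@points
  msgs <- character()
  if (!is.numeric(P) || ncol(P) != 3L)
    return("points must be an n x 3 numeric matrix")
  if (nrow(P) < 4L)
    msgs <- c(msgs, "at least 4 landmarks are required")
  if (any(!is.finite(P)))
    msgs <- c(msgs, "landmark coordinates must be finite")
  if (nrow(P) >= 2L) {
    nxt <- rbind(P[-1L, , drop = FALSE], P[1L, , drop = FALSE])
    d <- sqrt(rowSums((nxt - P)^2))
    if (any(d <= 0.1))
      msgs <- c(msgs, "consecutive landmarks must be more than 0.1 mm apart")
  }
  if (!length(msgs) && nrow(P) >= 4L && ring_self_crosses(P))
    msgs <- c(msgs, paste0("landmark ring self-crosses when projected on its",
                           " best-fit plane; reorder the points"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a LandmarkSet
#'
#' @param points n x 3 matrix (or coercible) of world mm coordinates, ordered
#'   along the rim as one closed loop.
#' @param label free-text label.
#' @return A \linkS4class{LandmarkSet}.
#' @export
landmarkSet <- function(points, label = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  new("LandmarkSet", points = points, label = as.character(label))
}

#' Anterior boundary fan surface
#'
#' The triangulated anterior boundary of the orbit: each rim landmark pair
#' (p_i, p_{i+1}) is joined to the landmark centroid, giving exactly n
#' triangles for n landmarks -- a topological disk bounded by the landmark
#' loop. Triangle winding is oriented so every normal has a positive dot
#' product with the anterior hint direction.
#'
#' @slot vertices (n+1) x 3 matrix: the n landmarks followed by their
#'   centroid.
#' @slot triangles n x 3 integer matrix of vertex indices
#'   (centroid, p_i, p_{i+1}).
#' @slot anterior_hint numeric(3) world direction pointing anteriorly.
#' @aliases FanSurface
#' @exportClass FanSurface
setClass("FanSurface",
  slots = c(vertices = "matrix", triangles = "matrix",
            anterior_hint = "numeric")
)

setValidity("FanSurface", function(object) {
  n <- nrow(object@vertices) - 1L
  msgs <- character()
  if (n < 3L) msgs <- c(msgs, "a fan surface needs at least 3 rim vertices")
  if (nrow(object@triangles) != n)
    msgs <- c(msgs, "a fan over n landmarks must have exactly n triangles")
  if (!all(object@triangles[, 1L] == n + 1L))
    msgs <- c(msgs, "every triangle must contain the centroid vertex")
  ctr <- colMeans(object@vertices[seq_len(n), , drop = FALSE])
  if (max(abs(ctr - object@vertices[n + 1L, ])) > 1e-8)
    msgs <- c(msgs, "last vertex must be the arithmetic mean of the landmarks")
  if (sum(object@anterior_hint^2) <= 0)
    msgs <- c(msgs, "anterior_hint must be a non-zero direction")
  if (length(msgs)) msgs else TRUE
})

#' Cavity segmentation parameters
#'
#' Controls the seeded initial cavity segmentation. The seed defaults to
#' "auto": the landmark-ring centroid displaced posteriorly (opposite the
#' anterior hint) by \code{seed_depth_mm}. Growth is bounded by the closed
#' bone shell, the anterior fan surface, a posterior depth cap and a radial
#' cap around the ring axis; the grown core is then dilated by
#' \code{dilate_mm} so the initial mask is over-inclusive (it deliberately
#' re-admits partial-volume bone, which the semi-automatic refinement
#' subtracts again).
#'
#' @slot mask_config a \linkS4class{MaskConfig}.
#' @slot seed_point numeric(3) world mm seed, or NA for "auto".
#' @slot seed_depth_mm depth of the auto seed behind the ring centroid
#'   (default 15 mm).
#' @slot posterior_extent_mm maximum growth depth behind the anterior plane
#'   (default 55 mm).
#' @slot radial_margin_mm growth cap beyond the largest ring radius
#'   (default 2 mm).
#' @slot shell_threshold_hu HU threshold of the barrier shell used only for
#'   region growing (default +200). Deliberately more permissive than the
#'   refinement's bone threshold: sub-voxel walls drop below +400 HU through
#'   partial volume, and a growth barrier must not thread such pinholes
#'   (the shape prior of an atlas-style first pass plays the same role).
#' @slot dilate_mm over-inclusion dilation of the grown core (default 1 mm),
#'   which re-admits the partial-volume bone rind for the refinement to
#'   subtract again.
#' @slot anterior_hint numeric(3) anterior direction (default -y, LPS).
#' @aliases SegmentationParams
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  slots = c(
    mask_config = "MaskConfig",
    seed_point = "numeric",
    seed_depth_mm = "numeric",
    posterior_extent_mm = "numeric",
    radial_margin_mm = "numeric",
    shell_threshold_hu = "numeric",
    dilate_mm = "numeric",
    anterior_hint = "numeric"
  )
)

setValidity("SegmentationParams", function(object) {
  msgs <- character()
  if (object@posterior_extent_mm <= 0)
    msgs <- c(msgs, "posterior_extent_mm must be positive")
  if (object@seed_depth_mm <= 0)
    msgs <- c(msgs, "seed_depth_mm must be positive")
  if (object@radial_margin_mm < 0)
    msgs <- c(msgs, "radial_margin_mm must be non-negative")
  if (object@dilate_mm < 0)
    msgs <- c(msgs, "dilate_mm must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct SegmentationParams
#'
#' @param mask_config a \linkS4class{MaskConfig}.
#' @param seed_point world mm seed point, or NA (default) for automatic
#'   placement at ring centroid + \code{seed_depth_mm} posteriorly.
#' @param seed_depth_mm auto-seed depth, default 15 mm.
#' @param posterior_extent_mm posterior growth cap, default 55 mm.
#' @param radial_margin_mm radial growth cap margin, default 2 mm.
#' @param shell_threshold_hu permissive barrier-shell threshold for region
#'   growing only, default +200 HU.
#' @param dilate_mm over-inclusion dilation, default 1 mm.
#' @param anterior_hint anterior world direction, default c(0, -1, 0) (LPS).
#' @return A \linkS4class{SegmentationParams}.
#' @export
segmentationParams <- function(mask_config = maskConfig(),
                               seed_point = NA_real_,
                               seed_depth_mm = 15,
                               posterior_extent_mm = 55,
                               radial_margin_mm = 2,
                               shell_threshold_hu = 200,
                               dilate_mm = 1,
                               anterior_hint = c(0, -1, 0)) {
  new("SegmentationParams", mask_config = mask_config,
      seed_point = as.numeric(seed_point),
      seed_depth_mm = as.numeric(seed_depth_mm),
      posterior_extent_mm = as.numeric(posterior_extent_mm),
      radial_margin_mm = as.numeric(radial_margin_mm),
      shell_threshold_hu = as.numeric(shell_threshold_hu),
      dilate_mm = as.numeric(dilate_mm),
      anterior_hint = as.numeric(anterior_hint))
}

#' Result of the orbital volume measurement pipeline
#'
#' Collects all intermediate masks, per-stage volumes and the stage log of
#' one run of \code{\link{measureOrbitalVolume}}.
#'
#' @slot auto_mask initial over-inclusive cavity mask.
#' @slot sa_mask after bone/air subtraction and largest component.
#' @slot clipped_mask final mask after anterior clipping and component
#'   cleanup; \code{volume_cc} is its volume.
#' @slot volume_cc final orbital volume in cc.
#' @slot stage_volumes_cc named numeric of per-stage volumes in cc.
#' @slot params_echo the \linkS4class{SegmentationParams} used.
#' @slot log character vector of structured stage messages.
#' @aliases OrbitalVolumeResult
#' @exportClass OrbitalVolumeResult
setClass("OrbitalVolumeResult",
  slots = c(
    auto_mask = "BinaryMask",
    sa_mask = "BinaryMask",
    clipped_mask = "BinaryMask",
    volume_cc = "numeric",
    stage_volumes_cc = "numeric",
    params_echo = "SegmentationParams",
    log = "character"
  )
)

#' Signed surface distance map
#'
#' Per-boundary-point signed distances (mm) from a test segmentation to a
#' reference segmentation: positive where the test boundary lies outside the
#' reference, negative inside, zero on the reference boundary itself.
#'
#' @slot points m x 3 matrix of test-boundary voxel centres (world mm).
#' @slot signed_distances signed distance in mm per point.
#' @slot summary list with \code{mean_signed_mm}, \code{mean_abs_mm} and
#'   \code{p95_abs_mm} (95th percentile of absolute distances, linear
#'   interpolation between order statistics, quantile type 7).
#' @aliases DistanceMap
#' @exportClass DistanceMap
setClass("DistanceMap",
  slots = c(points = "matrix", signed_distances = "numeric", summary = "list")
)

#' Intraclass correlation result
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (McGraw--Wong ICC(A,1)) with its 95\% F-based confidence
#' interval. The model label is fixed so the choice is auditable in every
#' report.
#'
#' @slot icc the ICC point estimate.
#' @slot ci_low,ci_high 95\% confidence bounds.
#' @slot model_label fixed text describing the ICC model.
#' @slot n_subjects,n_raters table dimensions.
#' @slot mean_squares named numeric: MSR (rows/subjects), MSC
#'   (columns/raters), MSE.
#' @aliases ICCResult
#' @exportClass ICCResult
setClass("ICCResult",
  slots = c(
    icc = "numeric", ci_low = "numeric", ci_high = "numeric",
    model_label = "character", n_subjects = "integer", n_raters = "integer",
    mean_squares = "numeric"
  )
)

setValidity("ICCResult", function(object) {
  if (object@ci_low > object@icc + 1e-12 ||
      object@ci_high < object@icc - 1e-12)
    "confidence interval must bracket the ICC estimate"
  else TRUE
})

#' Mask agreement report
#'
#' Assembles the validation battery for a test mask against a reference:
#' volumes in cc, their difference, the Dice coefficient and the signed
#' surface-distance summary. The paired t statistic and p value are filled
#' when cohort volume vectors are supplied (they are not defined for a
#' single mask pair) and are NA otherwise.
#'
#' @slot volume_test_cc,volume_ref_cc volumes in cc.
#' @slot mean_diff_cc \code{volume_test_cc - volume_ref_cc}.
#' @slot dice Dice coefficient in [0, 1].
#' @slot distance_map a \linkS4class{DistanceMap}.
#' @slot t_statistic,p_value paired t test over cohort volumes (NA for a
#'   single pair).
#' @aliases AgreementReport
#' @exportClass AgreementReport
setClass("AgreementReport",
  slots = c(
    volume_test_cc = "numeric", volume_ref_cc = "numeric",
    mean_diff_cc = "numeric", dice = "numeric",
    distance_map = "DistanceMap",
    t_statistic = "numeric", p_value = "numeric"
  )
)

setValidity("AgreementReport", function(object) {
  if (object@dice < 0 || object@dice > 1) "dice must lie in [0, 1]" else TRUE
})

#' Synthetic orbit phantom specification
#'
#' Parameters of the deterministic synthetic orbit-CT generator. The cavity
#' is a half-ellipsoid opening anteriorly (-y, LPS) whose closed-form volume
#' (2/3) pi a b c is the ground-truth anchor; it is bounded by a thin
#' high-HU wall, has an adjacent air-filled sinus block at the medial wall, a
#' narrow fissure-like corridor breaching the infero-medial wall into the
#' sinus, Gaussian partial-volume blur and additive acquisition noise.
#' Defaults give a 28.86 cc adult-scale orbit at the 0.5 mm acquisition
#' geometry.
#'
#' @slot cavity_semi_axes_mm numeric(3) = (a, b, c): lateral and vertical rim
#'   semi-axes and posterior depth; defaults (17.5, 17.5, 45).
#' @slot wall_thickness_mm bony wall thickness, default 1 mm.
#' @slot wall_hu wall intensity, default +1000 HU.
#' @slot cavity_hu soft-tissue cavity intensity, default +30 HU.
#' @slot sinus_hu sinus air intensity, default -1000 HU.
#' @slot background_hu surrounding tissue intensity, default 0 HU.
#' @slot fissure_width_mm diameter of the wall-breaching corridor, default
#'   2 mm.
#' @slot blur_sigma_mm Gaussian partial-volume sigma, default 0.5 mm.
#' @slot noise_sd_hu additive Gaussian noise SD, default 10 HU.
#' @slot spacing_mm voxel spacing, default (0.5, 0.5, 0.5) mm.
#' @slot seed RNG seed for the noise (integer).
#' @aliases PhantomSpec
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  slots = c(
    cavity_semi_axes_mm = "numeric",
    wall_thickness_mm = "numeric",
    wall_hu = "numeric",
    cavity_hu = "numeric",
    sinus_hu = "numeric",
    background_hu = "numeric",
    fissure_width_mm = "numeric",
    blur_sigma_mm = "numeric",
    noise_sd_hu = "numeric",
    spacing_mm = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@cavity_semi_axes_mm) != 3L ||
      any(object@cavity_semi_axes_mm <= 0))
    msgs <- c(msgs, "cavity semi-axes must be 3 positive numbers")
  if (object@wall_thickness_mm <= 0)
    msgs <- c(msgs, "wall_thickness_mm must be positive")
  if (object@fissure_width_mm < 0)
    msgs <- c(msgs, "fissure_width_mm must be non-negative")
  ab <- object@cavity_semi_axes_mm[c(1L, 2L)]
  if (object@fissure_width_mm >= 2 * min(ab))
    msgs <- c(msgs, "fissure_width_mm must be below twice the smallest rim semi-axis")
  if (length(object@spacing_mm) != 3L || any(object@spacing_mm <= 0))
    msgs <- c(msgs, "spacing_mm must be 3 positive numbers")
  if (object@blur_sigma_mm < 0 || object@noise_sd_hu < 0)
    msgs <- c(msgs, "blur_sigma_mm and noise_sd_hu must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhantomSpec
#'
#' @param cavity_semi_axes_mm (a, b, c) semi-axes in mm, default
#'   (17.5, 17.5, 45).
#' @param wall_thickness_mm wall thickness, default 1 mm.
#' @param wall_hu,cavity_hu,sinus_hu,background_hu tissue intensities in HU.
#' @param fissure_width_mm corridor diameter, default 2 mm.
#' @param blur_sigma_mm partial-volume blur sigma, default 0.5 mm.
#' @param noise_sd_hu additive noise SD, default 10 HU.
#' @param spacing_mm voxel spacing, default 0.5 mm isotropic.
#' @param seed noise RNG seed, default 1.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(cavity_semi_axes_mm = c(17.5, 17.5, 45),
                        wall_thickness_mm = 1.0, wall_hu = 1000,
                        cavity_hu = 30, sinus_hu = -1000, background_hu = 0,
                        fissure_width_mm = 2.0, blur_sigma_mm = 0.5,
                        noise_sd_hu = 10, spacing_mm = c(0.5, 0.5, 0.5),
                        seed = 1L) {
  new("PhantomSpec",
      cavity_semi_axes_mm = as.numeric(cavity_semi_axes_mm),
      wall_thickness_mm = as.numeric(wall_thickness_mm),
      wall_hu = as.numeric(wall_hu), cavity_hu = as.numeric(cavity_hu),
      sinus_hu = as.numeric(sinus_hu),
      background_hu = as.numeric(background_hu),
      fissure_width_mm = as.numeric(fissure_width_mm),
      blur_sigma_mm = as.numeric(blur_sigma_mm),
      noise_sd_hu = as.numeric(noise_sd_hu),
      spacing_mm = as.numeric(spacing_mm), seed = as.integer(seed))
}

#' Generated phantom case
#'
#' One rendered synthetic orbit: the HU volume, the pre-blur ground-truth
#' cavity label (blur models acquisition, not anatomy), the rim landmark
#' ring, and the closed-form half-ellipsoid volume.
#'
#' @slot volume rendered \linkS4class{HUVolume}.
#' @slot truth_mask pre-blur cavity \linkS4class{BinaryMask}.
#' @slot landmarks \linkS4class{LandmarkSet} on the anterior rim ellipse.
#' @slot analytic_volume_cc (2/3) pi a b c / 1000.
#' @slot spec_echo the generating \linkS4class{PhantomSpec}.
#' @aliases PhantomCase
#' @exportClass PhantomCase
setClass("PhantomCase",
  slots = c(
    volume = "HUVolume",
    truth_mask = "BinaryMask",
    landmarks = "LandmarkSet",
    analytic_volume_cc = "numeric",
    spec_echo = "PhantomSpec"
  )
)
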