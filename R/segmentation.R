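#' @include AllClasses.R utils.R mask-ops.R anterior.R
NULL

# Resolve the seed point: explicit world point, or ring centroid displaced
# posteriorly (against the anterior hint) by seed_depth_mm.
resolve_seed <- function(params, lm) {
  if (length(params@seed_point) == 3L && all(is.finite(params@seed_point)))
    return(params@seed_point)
  if (is.null(lm))
    orb_stop("orbvol_seed_error",
             "automatic seed placement requires a landmark ring")
  colMeans(lm@points) - params@seed_depth_mm * normalize3(params@anterior_hint)
}

#' Initial (over-inclusive) cavity segmentation
#'
#' Stand-in for an atlas-style automatic first pass, reproducing its
#' pipeline role: an over-inclusive initial cavity mask that may contain
#' residual bone and air, later corrected by \code{\link{refineSA}} and
#' anterior clipping. The algorithm: (1) barrier shell at the permissive
#' \code{shell_threshold_hu} (+200 HU default -- sub-voxel walls drop below
#' the +400 HU bone threshold through partial volume, and a growth barrier
#' must not thread such pinholes), morphologically closed with a physical
#' ball so wall gaps and the fissure are sealed; (2) seeded region growing
#' through non-shell space, bounded anteriorly by the fan surface,
#' posteriorly by \code{posterior_extent_mm} behind it, and radially by the
#' largest ring radius plus \code{radial_margin_mm} (a shape prior standing
#' in for the atlas); (3) Euclidean dilation of the grown core by
#' \code{dilate_mm}, which deliberately re-admits partial-volume bone at
#' the walls so the initial mask is a superset of the cavity.
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param params a \linkS4class{SegmentationParams}.
#' @param lm a \linkS4class{LandmarkSet} rim ring (needed for the anterior
#'   boundary and the automatic seed).
#' @param surface optionally a prebuilt \linkS4class{FanSurface} (defaults
#'   to the fan over \code{lm} with the params' anterior hint).
#' @return A \linkS4class{BinaryMask}.
#' @export
segmentCavityAuto <- function(vol, params, lm, surface = NULL) {
  cfg <- params@mask_config
  if (is.null(surface)) surface <- buildFanSurface(lm, params@anterior_hint)
  geom <- vol@geometry

  shell_raw <- thresholdMask(vol, lo = params@shell_threshold_hu)
  shell <- morphologicalClose(shell_raw, cfg@closing_radius_mm)

  fg <- fan_signed_grid(surface, geom)
  fr <- fan_frame(surface)
  n <- fr$n
  ring_r <- sqrt(rowSums(sweep(surface@vertices[seq_len(n), , drop = FALSE],
                               2L, fr$center)^2))
  r_cap <- max(ring_r) + params@radial_margin_mm

  allowed <- !shell@values & fg$s <= 0 &
    fg$s >= -params@posterior_extent_mm & fg$r <= r_cap

  seed <- resolve_seed(params, lm)
  seed_idx <- round(world_to_voxel(geom, matrix(seed, 1L, 3L)))
  if (any(seed_idx < 0) || any(seed_idx > geom@shape - 1L))
    orb_stop("orbvol_seed_error",
             "seed point (%.1f, %.1f, %.1f) mm lies outside the volume",
             seed[1], seed[2], seed[3])
  seed_lin <- 1L + seed_idx[1] + geom@shape[1] *
    (seed_idx[2] + geom@shape[2] * seed_idx[3])
  if (shell@values[seed_lin])
    orb_stop("orbvol_seed_error",
             "seed point lies inside (closed) bone; choose a seed inside the orbital cavity")
  if (!allowed[seed_lin])
    orb_stop("orbvol_leak_error", paste0(
      "seed point lies outside the orbital search region (anterior of the ",
      "rim surface, beyond the posterior extent, or beyond the radial cap); ",
      "region growing would capture the exterior"))

  allowed_mask <- new("BinaryMask", geometry = geom,
                      values = array(allowed, dim = dim(vol@values)))
  lab <- label_components(allowed_mask, cfg@connectivity)
  core <- new("BinaryMask", geometry = geom, values = lab == lab[seed_lin])

  bound_cc <- surfaceArea(surface) * params@posterior_extent_mm / 1000
  if (maskVolume(core) > 3 * bound_cc)
    orb_stop("orbvol_leak_error", paste0(
      "region growing escaped to %.1f cc, over 3x the %.1f cc anterior-",
      "surface x posterior-extent bounding region; a wall gap (e.g. an ",
      "unsealed inferior-orbital-fissure-like defect) is the likely cause"),
      maskVolume(core), bound_cc)

  mask_dilate(core, params@dilate_mm)
}

#' Semi-automatic (SA) refinement by bone/air mask subtraction
#'
#' The core of the semi-automatic method: a bone mask (voxels at the bone
#' threshold, +400 HU or more, by default) and an air mask (air threshold,
#' -600 HU or less) are created and subtracted from the initial
#' segmentation; the largest connected component is then kept, because
#' subtraction can disconnect debris. The result is always a subset of the
#' input mask.
#'
#' @param auto_mask initial cavity \linkS4class{BinaryMask}.
#' @param vol the \linkS4class{HUVolume} (same geometry).
#' @param cfg a \linkS4class{MaskConfig}.
#' @return A \linkS4class{BinaryMask}.
#' @export
refineSA <- function(auto_mask, vol, cfg = maskConfig()) {
  check_same_geometry(auto_mask, vol, "mask and volume")
  bone <- thresholdMask(vol, lo = cfg@bone_threshold_hu)
  air <- thresholdMask(vol, hi = cfg@air_threshold_hu)
  out <- maskSubtract(maskSubtract(auto_mask, bone), air)
  largestComponent(out, cfg@connectivity)
}

#' Measure orbital volume (full semi-automatic pipeline)
#'
#' Runs the complete measurement: initial over-inclusive segmentation,
#' bone/air subtraction (SA), anterior clipping at the landmark fan surface,
#' largest-component cleanup, and voxel-count volume in cc. All intermediate
#' masks, per-stage volumes and a structured stage log are retained. The
#' pipeline contains no randomness: identical inputs give bit-identical
#' results.
#'
#' @param vol an \linkS4class{HUVolume}.
#' @param lm rim \linkS4class{LandmarkSet}.
#' @param params a \linkS4class{SegmentationParams}.
#' @return An \linkS4class{OrbitalVolumeResult}.
#' @export
measureOrbitalVolume <- function(vol, lm, params = segmentationParams()) {
  surface <- buildFanSurface(lm, params@anterior_hint)
  log <- character()
  step <- function(stage, msg) sprintf("stage=%s msg=%s", stage, msg)

  auto <- segmentCavityAuto(vol, params, lm, surface)
  log <- c(log, step("auto", fmt_cc(maskVolume(auto))))

  sa <- refineSA(auto, vol, params@mask_config)
  log <- c(log, step("sa", fmt_cc(maskVolume(sa))))

  clipped <- clipAnterior(sa, surface)
  log <- c(log, step("clip", fmt_cc(maskVolume(clipped))))

  final <- largestComponent(clipped, params@mask_config@connectivity)
  log <- c(log, step("component", fmt_cc(maskVolume(final))))

  stage_volumes <- c(auto = maskVolume(auto), sa = maskVolume(sa),
                     clipped = maskVolume(clipped),
                     final = maskVolume(final))
  new("OrbitalVolumeResult", auto_mask = auto, sa_mask = sa,
      clipped_mask = final, volume_cc = maskVolume(final),
      stage_volumes_cc = stage_volumes, params_echo = params, log = log)
}
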