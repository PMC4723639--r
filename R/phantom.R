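#' @include AllClasses.R utils.R mask-ops.R
NULL

# Closed-form half-ellipsoid volume in cc.
analytic_half_ellipsoid_cc <- function(semi) {
  (2 / 3) * pi * semi[1] * semi[2] * semi[3] / 1000
}

# Phantom layout in world mm (LPS; anterior = -y). The cavity is a
# half-ellipsoid with rim plane y = y0 opening anteriorly, rim semi-axes
# a (x, lateral) and b (z, vertical), depth c along +y.
phantom_layout <- function(spec) {
  semi <- spec@cavity_semi_axes_mm
  a <- semi[1]; b <- semi[2]; cc <- semi[3]
  t <- spec@wall_thickness_mm
  y0 <- 6
  xc <- 3 + t + a
  zc <- 3 + t + b
  sinus_depth <- 16
  extent <- c(
    xc + max(a + t, 0.6 * a + sinus_depth) + 3,
    y0 + cc + t + 6,
    zc + b + t + 3
  )
  list(a = a, b = b, c = cc, t = t, y0 = y0, xc = xc, zc = zc,
       extent = extent, sinus_depth = sinus_depth)
}

# Direction of the fissure corridor (toward the infero-medial wall and the
# sinus beyond it).
fissure_axis <- function(lay) {
  list(p0 = c(lay$xc, lay$y0 + 0.35 * lay$c, lay$zc),
       d = normalize3(c(0.8, 0.3, -0.52)))
}

# Voxel-centre coordinate arrays for an axis-aligned geometry, expanded to
# the full grid (kept as vectors + index helpers to limit memory).
grid_coords <- function(geom) {
  cw <- axis_world_coords(geom)
  d <- as.integer(geom@shape)
  list(
    X = array(rep(cw[[1]], times = d[2] * d[3]), d),
    Y = array(rep(rep(cw[[2]], each = d[1]), times = d[3]), d),
    Z = array(rep(cw[[3]], each = d[1] * d[2]), d)
  )
}

# Logical cavity mask for semi-axes inflated by `offset` mm (a surface
# erosion/dilation of the half-ellipsoid in its analytic form).
phantom_cavity_values <- function(lay, co, offset = 0) {
  a <- lay$a + offset; b <- lay$b + offset; cc <- lay$c + offset
  q <- ((co$X - lay$xc) / a)^2 + ((co$Y - lay$y0) / cc)^2 +
    ((co$Z - lay$zc) / b)^2
  q <= 1 & co$Y >= lay$y0
}

# Pointwise HU classification of the phantom anatomy at arbitrary world
# coordinates (vectors or arrays). The pieces:
#  - cavity: half-ellipsoid opening anteriorly (y >= y0), at cavity_hu;
#  - wall: analytic shell between the cavity and the ellipsoid grown by the
#    wall thickness (an analytic band avoids the staircase thinning a
#    voxel-distance criterion shows on oblique patches); the bony rim also
#    continues 2 mm anterior of the rim plane around the rim annulus (a
#    knife-edge wall ending exactly at the plane would blur below the bone
#    threshold at its free edge) while the opening disk stays open;
#  - fissure: a corridor of fissure_width_mm toward the sinus through the
#    infero-medial wall, running through a locally thickened bone collar (a
#    slot between bone plates, as at the real inferior orbital fissure), so
#    that a narrow corridor is a tube the closing ball cannot thread while a
#    doubled-width corridor stays open;
#  - sinus: air block hugging the medial wall with a 1 mm soft-tissue
#    standoff (mucosa-lined bone: air directly behind a thin wall would
#    hollow out its partial-volume bone band).
phantom_hu_at <- function(lay, spec, x, y, z) {
  qe <- function(da) ((x - lay$xc) / (lay$a + da))^2 +
    ((y - lay$y0) / (lay$c + da))^2 + ((z - lay$zc) / (lay$b + da))^2
  cavity <- qe(0) <= 1 & y >= lay$y0
  rim_annulus <- ((x - lay$xc) / lay$a)^2 + ((z - lay$zc) / lay$b)^2 >= 1
  wall <- qe(lay$t) <= 1 & !cavity &
    (y >= lay$y0 | (y >= lay$y0 - 2 & rim_annulus))

  corridor <- NULL
  if (spec@fissure_width_mm > 0) {
    ax <- fissure_axis(lay)
    rx <- x - ax$p0[1]; ry <- y - ax$p0[2]; rz <- z - ax$p0[3]
    tau <- rx * ax$d[1] + ry * ax$d[2] + rz * ax$d[3]
    d_line2 <- (rx - tau * ax$d[1])^2 + (ry - tau * ax$d[2])^2 +
      (rz - tau * ax$d[3])^2
    collar <- tau > 0 & d_line2 <= (spec@fissure_width_mm / 2 + 3)^2 &
      qe(lay$t + 2.5) <= 1 & !cavity & y >= lay$y0
    wall <- wall | collar
    corridor <- tau > 0 & d_line2 <= (spec@fissure_width_mm / 2)^2
  }

  sinus <- x >= lay$xc + 0.6 * lay$a &
    x <= lay$xc + 0.6 * lay$a + lay$sinus_depth &
    y >= lay$y0 + 8 & y <= lay$y0 + 0.65 * lay$c &
    z >= lay$zc - 0.8 * lay$b & z <= lay$zc + 0.25 * lay$b &
    qe(lay$t + 1) > 1

  hu <- array(spec@background_hu, dim = dim(as.array(x)))
  hu[sinus] <- spec@sinus_hu
  hu[wall] <- spec@wall_hu
  if (!is.null(corridor)) hu[wall & corridor] <- spec@cavity_hu
  hu[cavity] <- spec@cavity_hu
  hu
}

#' Generate a synthetic orbit CT phantom
#'
#' Renders the deterministic phantom described by a
#' \linkS4class{PhantomSpec}: a half-ellipsoid soft-tissue cavity opening
#' anteriorly, a thin high-HU bony wall around it (except the anterior
#' opening), an air-filled sinus block hugging the medial wall, a narrow
#' fissure-like corridor breaching the infero-medial wall into the sinus
#' (the analogue of the inferior orbital fissure, the dominant source of
#' segmentation discrepancy), Gaussian partial-volume blur and additive
#' Gaussian noise. The ground-truth label is the pre-blur cavity (blur
#' models acquisition, not anatomy); rim landmarks are sampled about every
#' 8 mm on the exact rim ellipse. All randomness flows from the spec seed;
#' the truth mask and landmarks carry none.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param hu render HU values (default TRUE). \code{hu = FALSE} skips
#'   rendering (volume filled with background) for geometry-only uses such
#'   as rater simulation or voxelisation studies.
#' @param extent_mm optional fixed grid extent (mm, numeric(3)); the cavity
#'   plus walls and margins must fit, otherwise a fit error is raised. By
#'   default the grid is sized to fit the spec.
#' @return A \linkS4class{PhantomCase}.
#' @export
generatePhantom <- function(spec, hu = TRUE, extent_mm = NULL) {
  lay <- phantom_layout(spec)
  extent <- lay$extent
  if (!is.null(extent_mm)) {
    if (any(extent_mm < extent))
      orb_stop("orbvol_fit_error",
               "cavity plus walls and margins (%.0f x %.0f x %.0f mm) does not fit the requested %.0f x %.0f x %.0f mm grid",
               extent[1], extent[2], extent[3],
               extent_mm[1], extent_mm[2], extent_mm[3])
    extent <- extent_mm
  }
  sp <- spec@spacing_mm
  shape <- as.integer(ceiling(extent / sp))
  geom <- voxelGeometry(shape, spacing = sp, origin = sp / 2)
  co <- grid_coords(geom)

  cavity <- phantom_cavity_values(lay, co)
  truth <- new("BinaryMask", geometry = geom, values = cavity)

  # rim landmark ring on the exact rim ellipse, ~8 mm apart
  per <- pi * (3 * (lay$a + lay$b) -
                 sqrt((3 * lay$a + lay$b) * (lay$a + 3 * lay$b)))
  n_lm <- max(4L, as.integer(round(per / 8)))
  phi <- pi / 2 + 2 * pi * (seq_len(n_lm) - 1L) / n_lm
  lms <- landmarkSet(cbind(lay$xc + lay$a * cos(phi),
                           rep(lay$y0, n_lm),
                           lay$zc + lay$b * sin(phi)),
                     label = "synthetic orbit rim")

  if (hu) {
    vals <- phantom_hu_at(lay, spec, co$X, co$Y, co$Z)
    if (spec@blur_sigma_mm > 0) {
      # partial-volume rendering: voxels straddling a tissue interface are
      # supersampled (3x3x3 subcells) so a sub-voxel wall contributes its
      # true fractional HU instead of an all-or-nothing voxel (a binary
      # rendering punches spurious holes through bands thinner than the
      # voxel). Interface voxels are detected by comparing the corner-point
      # classifications with the centre. A blur sigma of 0 keeps the sharp
      # idealised rendering.
      iface <- array(FALSE, dim(cavity))
      for (ox in c(-0.5, 0.5)) for (oy in c(-0.5, 0.5))
        for (oz in c(-0.5, 0.5)) {
          h <- phantom_hu_at(lay, spec, co$X + ox * sp[1],
                             co$Y + oy * sp[2], co$Z + oz * sp[3])
          iface <- iface | (h != vals)
        }
      idx <- which(iface)
      if (length(idx)) {
        xi <- co$X[idx]; yi <- co$Y[idx]; zi <- co$Z[idx]
        acc <- numeric(length(idx))
        for (ox in (-1:1) / 3) for (oy in (-1:1) / 3)
          for (oz in (-1:1) / 3) {
            acc <- acc + phantom_hu_at(lay, spec, xi + ox * sp[1],
                                       yi + oy * sp[2], zi + oz * sp[3])
          }
        vals[idx] <- acc / 27
      }
      # blur_sigma_mm is the total Gaussian-equivalent partial-volume
      # width; in-voxel averaging already contributes spacing^2/12 of
      # variance, so the scanner-PSF part is the remainder
      psf <- sqrt(pmax(0, spec@blur_sigma_mm^2 - sp^2 / 12))
      vals <- array(cpp_gauss_blur(as.numeric(vals), dim(cavity),
                                   psf / sp), dim(cavity))
    }
    if (spec@noise_sd_hu > 0) {
      noise <- with_seed(spec@seed,
                         stats::rnorm(length(vals), 0, spec@noise_sd_hu))
      vals <- vals + array(noise, dim(cavity))
    }
    vol <- new("HUVolume", geometry = geom, values = vals)
  } else {
    vol <- new("HUVolume", geometry = geom,
               values = array(spec@background_hu, dim(cavity)))
  }

  new("PhantomCase", volume = vol, truth_mask = truth, landmarks = lms,
      analytic_volume_cc = analytic_half_ellipsoid_cc(spec@cavity_semi_axes_mm),
      spec_echo = spec)
}

#' Parameter sweep of phantom specifications
#'
#' A fixed stratified design over the phantom's difficulty parameters: wall
#' thickness takes \code{n} evenly spaced values over 0.5--1.5 mm, crossed
#' with a cycling partial-volume blur of 0.3--0.7 mm, covering both ranges
#' systematically in \code{n} cases. Per-case noise seeds derive from
#' \code{seed}. This is the battery used to characterise volume recovery
#' across acquisition difficulty.
#'
#' @param n number of cases (default 10).
#' @param seed base seed; case i uses \code{seed + i}.
#' @return List of \linkS4class{PhantomSpec} objects.
#' @export
phantomSweep <- function(n = 10L, seed = 1L) {
  tw <- seq(0.5, 1.5, length.out = n)
  bs <- rep(seq(0.3, 0.7, length.out = 4L), length.out = n)
  lapply(seq_len(n), function(i)
    phantomSpec(wall_thickness_mm = tw[i], blur_sigma_mm = bs[i],
                seed = as.integer(seed) + i))
}

#' Simulate independent raters on phantom cases
#'
#' Produces a subjects x raters table of volumes for exercising
#' \code{\link{iccAgreement}}, mirroring a two-observer manual segmentation
#' design. Each rater's segmentation of each phantom is the ground-truth
#' cavity surface eroded or dilated by a rater- and subject-specific random
#' offset drawn uniformly within \code{[-boundary_jitter_mm,
#' +boundary_jitter_mm]} (applied analytically to the half-ellipsoid and
#' re-voxelised), emulating consistent under- or over-tracing of the
#' boundary. Offsets scale linearly with the jitter for a fixed seed, so
#' agreement degrades monotonically as jitter grows. Jitter 0 reproduces
#' the truth volume for every rater.
#'
#' @param cases a \linkS4class{PhantomCase} or list of them (subjects).
#' @param n_raters number of raters (>= 2, default 2).
#' @param boundary_jitter_mm maximum absolute boundary offset (mm).
#' @param seed RNG seed for the offsets.
#' @return numeric matrix (subjects x raters) of volumes in cc.
#' @export
simulateRaters <- function(cases, n_raters = 2L, boundary_jitter_mm = 0.25,
                           seed = 1L) {
  if (methods::is(cases, "PhantomCase")) cases <- list(cases)
  if (n_raters < 2L)
    orb_stop("orbvol_degenerate_error", "at least 2 raters are required")
  if (boundary_jitter_mm < 0)
    orb_stop("orbvol_degenerate_error", "boundary jitter must be >= 0")
  ns <- length(cases)
  u <- with_seed(seed, matrix(stats::runif(ns * n_raters, -1, 1),
                              ns, n_raters))
  out <- matrix(NA_real_, ns, n_raters)
  for (i in seq_len(ns)) {
    case <- cases[[i]]
    lay <- phantom_layout(case@spec_echo)
    geom <- case@truth_mask@geometry
    co <- grid_coords(geom)
    voxvol <- prod(geom@spacing) / 1000
    for (r in seq_len(n_raters)) {
      off <- boundary_jitter_mm * u[i, r]
      if (off == 0) {
        out[i, r] <- maskVolume(case@truth_mask)
      } else {
        out[i, r] <- sum(phantom_cavity_values(lay, co, off)) * voxvol
      }
    }
  }
  dimnames(out) <- list(paste0("subject", seq_len(ns)),
                        paste0("rater", seq_len(n_raters)))
  out
}
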