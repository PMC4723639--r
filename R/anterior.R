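#' @include AllClasses.R utils.R mask-ops.R
NULL

#' Build the anterior fan surface
#'
#' Triangulates the anterior boundary of the orbit as a fan: every pair of
#' consecutive rim landmarks is connected to the landmark centre of gravity,
#' giving exactly one triangle per landmark. Each triangle's winding is
#' flipped if needed so its normal points along the anterior hint.
#' Degenerate (collinear) triangles raise a warning and are kept with zero
#' area.
#'
#' @param lm a \linkS4class{LandmarkSet}.
#' @param anterior_hint non-zero world direction pointing anteriorly
#'   (default -y, the anterior axis of the LPS patient frame).
#' @return A \linkS4class{FanSurface}.
#' @export
buildFanSurface <- function(lm, anterior_hint = c(0, -1, 0)) {
  if (sum(anterior_hint^2) <= 0)
    orb_stop("orbvol_degenerate_error", "anterior_hint must be non-zero")
  P <- lm@points
  n <- nrow(P)
  ctr <- colMeans(P)
  tri <- cbind(rep(n + 1L, n), seq_len(n), c(seq_len(n)[-1L], 1L))
  storage.mode(tri) <- "integer"
  n_degenerate <- 0L
  for (i in seq_len(n)) {
    a <- P[tri[i, 2L], ] - ctr
    b <- P[tri[i, 3L], ] - ctr
    nrm <- cross3(a, b)
    area2 <- sqrt(sum(nrm^2))
    if (area2 / 2 < 1e-6) {
      n_degenerate <- n_degenerate + 1L
    } else if (sum(nrm * anterior_hint) < 0) {
      tri[i, c(2L, 3L)] <- tri[i, c(3L, 2L)]
    }
  }
  if (n_degenerate > 0L)
    warning(sprintf("%d degenerate (near-zero area) fan triangle(s) kept",
                    n_degenerate), call. = FALSE)
  new("FanSurface", vertices = rbind(P, centroid = ctr), triangles = tri,
      anterior_hint = as.numeric(anterior_hint))
}

#' Total area of a fan surface
#'
#' Sum of the triangle areas (cross-product formula), in mm^2.
#'
#' @param s a \linkS4class{FanSurface}.
#' @return Area in mm^2.
#' @export
surfaceArea <- function(s) {
  V <- s@vertices
  tri <- s@triangles
  a <- V[tri[, 2L], , drop = FALSE] - V[tri[, 1L], , drop = FALSE]
  b <- V[tri[, 3L], , drop = FALSE] - V[tri[, 1L], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# Precomputed per-sector frame of a fan surface: ring angles, sector
# boundaries (on the ring's best-fit plane, positively oriented), and
# per-sector supporting-plane normals oriented along the anterior hint.
fan_frame <- function(surface) {
  n <- nrow(surface@vertices) - 1L
  P <- surface@vertices[seq_len(n), , drop = FALSE]
  ctr <- surface@vertices[n + 1L, ]
  hint <- normalize3(surface@anterior_hint)
  pl <- best_fit_plane(P, hint)
  rel <- sweep(P, 2L, ctr)
  u1 <- as.numeric(rel %*% pl$e1)
  u2 <- as.numeric(rel %*% pl$e2)
  # orient the in-plane frame so the ring runs counter-clockwise
  if (sum(u1 * c(u2[-1L], u2[1L]) - u2 * c(u1[-1L], u1[1L])) < 0) {
    pl$e2 <- -pl$e2
    u2 <- -u2
  }
  theta <- atan2(u2, u1)
  arcs <- (theta[c(2:n, 1L)] - theta) %% (2 * pi)
  star <- abs(sum(arcs) - 2 * pi) < 1e-9
  # per-sector supporting plane normal (centroid, p_i, p_{i+1})
  nxt <- rbind(P[-1L, , drop = FALSE], P[1L, , drop = FALSE])
  a <- sweep(P, 2L, ctr)
  b <- sweep(nxt, 2L, ctr)
  N <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(N^2))
  degen <- len < 1e-12
  if (any(degen)) {
    N[degen, ] <- matrix(pl$normal, sum(degen), 3, byrow = TRUE)
    len[degen] <- 1
  }
  N <- N / len
  flip <- as.numeric(N %*% hint) < 0
  N[flip, ] <- -N[flip, ]
  list(n = n, center = ctr, plane = pl, theta = theta, arcs = arcs,
       star = star, normals = N)
}

# Sector index of world points `W` (n x 3) for a precomputed fan frame.
# Star-shaped rings partition the full circle; otherwise each point goes to
# the sector whose angular midpoint is nearest (the documented fallback).
fan_sector <- function(fr, W) {
  rel <- sweep(W, 2L, fr$center)
  phi <- atan2(as.numeric(rel %*% fr$plane$e2),
               as.numeric(rel %*% fr$plane$e1))
  psi <- (phi - fr$theta[1L]) %% (2 * pi)
  if (fr$star) {
    bounds <- c(0, cumsum(fr$arcs))
    bounds[fr$n + 1L] <- 2 * pi + 1e-12
    pmin(findInterval(psi, bounds), fr$n)
  } else {
    mids <- ((fr$theta - fr$theta[1L]) %% (2 * pi)) + fr$arcs / 2
    dist <- abs(outer(psi, mids, "-"))
    dist <- pmin(dist, 2 * pi - dist)
    max.col(-dist, ties.method = "first")
  }
}

# Signed anterior distance (mm) of world points against a fan surface:
# positive = anterior of the supporting plane of the point's radial sector.
# Also returns the in-plane radial distance from the centroid.
fan_signed <- function(fr, W) {
  sec <- fan_sector(fr, W)
  rel <- sweep(W, 2L, fr$center)
  s <- rowSums(rel * fr$normals[sec, , drop = FALSE])
  r <- sqrt(as.numeric(rel %*% fr$plane$e1)^2 +
            as.numeric(rel %*% fr$plane$e2)^2)
  list(s = s, r = r)
}

# Signed anterior distance for every voxel centre of a geometry, as an
# array (chunked to bound peak memory).
fan_signed_grid <- function(surface, geom, chunk = 2e6) {
  fr <- fan_frame(surface)
  nvox <- prod(geom@shape)
  s <- numeric(nvox)
  r <- numeric(nvox)
  start <- 1
  dims <- as.integer(geom@shape)
  while (start <= nvox) {
    end <- min(start + chunk - 1, nvox)
    idx0 <- arrayInd(start:end, dims) - 1
    W <- voxel_to_world(geom, idx0)
    fs <- fan_signed(fr, W)
    s[start:end] <- fs$s
    r[start:end] <- fs$r
    start <- end + 1
  }
  list(s = array(s, dims), r = array(r, dims))
}

#' Clip a mask at the anterior fan surface
#'
#' Removes every voxel whose centre lies on the anterior side of the fan
#' surface ("excess anterior volume ... removed"). The side is decided per
#' voxel by the signed side of the supporting plane of the fan triangle
#' whose radial sector (about the centroid, in the ring's best-fit plane)
#' contains the voxel's projection; voxels outside all sectors use the
#' nearest sector. Voxel centres decide membership -- a voxel is wholly kept
#' or removed -- so clipping is idempotent and consistent with voxel-count
#' volumes. For a planar landmark ring this reduces exactly to a half-space
#' test against that plane.
#'
#' @param m a \linkS4class{BinaryMask}.
#' @param s a \linkS4class{FanSurface} in the same world frame.
#' @return A \linkS4class{BinaryMask}, subset of \code{m}.
#' @export
clipAnterior <- function(m, s) {
  if (!any(m@values)) return(m)
  fr <- fan_frame(s)
  keep <- m@values
  idx_true <- which(keep)
  chunk <- 2e6
  start <- 1
  while (start <= length(idx_true)) {
    end <- min(start + chunk - 1, length(idx_true))
    ids <- idx_true[start:end]
    idx0 <- arrayInd(ids, dim(keep)) - 1
    W <- voxel_to_world(m@geometry, idx0)
    fs <- fan_signed(fr, W)
    keep[ids[fs$s > 0]] <- FALSE
    start <- end + 1
  }
  new("BinaryMask", geometry = m@geometry, values = keep)
}

#' Resample a landmark ring at uniform arc-length spacing
#'
#' Piecewise-linear arc-length resampling of the closed rim loop to a target
#' point spacing; normalises rings digitised at uneven density toward the
#' recommended 0.5--1 cm landmark spacing. The first point is preserved.
#'
#' @param lm a \linkS4class{LandmarkSet}.
#' @param target_spacing_mm desired spacing between consecutive points (mm).
#' @return A resampled \linkS4class{LandmarkSet}.
#' @export
ringResample <- function(lm, target_spacing_mm) {
  if (target_spacing_mm <= 0)
    orb_stop("orbvol_threshold_error", "target_spacing_mm must be positive")
  P <- lm@points
  n <- nrow(P)
  Pc <- rbind(P, P[1L, ])
  seg <- sqrt(rowSums(diff(Pc)^2))
  cum <- c(0, cumsum(seg))
  per <- cum[n + 1L]
  n_new <- max(4L, as.integer(round(per / target_spacing_mm)))
  at <- (seq_len(n_new) - 1L) * per / n_new
  seg_idx <- pmin(findInterval(at, cum, rightmost.closed = TRUE), n)
  frac <- (at - cum[seg_idx]) / seg[seg_idx]
  Q <- Pc[seg_idx, , drop = FALSE] +
    (Pc[seg_idx + 1L, , drop = FALSE] - Pc[seg_idx, , drop = FALSE]) * frac
  landmarkSet(Q, label = lm@label)
}
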