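# Internal helpers: classed conditions, local RNG, world/voxel coordinates.

orb_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "orbvol_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so no global state leaks.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Geometry equality within tolerance (1e-6 mm / unitless).
same_geometry <- function(a, b, tol = 1e-6) {
  identical(a@shape, b@shape) &&
    max(abs(a@spacing - b@spacing)) <= tol &&
    max(abs(a@origin - b@origin)) <= tol &&
    max(abs(a@directions - b@directions)) <= tol
}

check_same_geometry <- function(a, b, what = "masks") {
  if (!same_geometry(a@geometry, b@geometry))
    orb_stop("orbvol_geometry_error",
             "%s do not share the same voxel geometry", what)
  invisible(TRUE)
}

# World coordinates (rows) of zero-based voxel indices (n x 3 matrix).
voxel_to_world <- function(geom, idx0) {
  sweep(idx0 %*% t(geom@directions %*% diag(geom@spacing)), 2L,
        geom@origin, "+")
}

# Continuous zero-based voxel coordinates of world points (n x 3).
world_to_voxel <- function(geom, world) {
  rel <- sweep(world, 2L, geom@origin, "-") %*% geom@directions
  sweep(rel, 2L, geom@spacing, "/")
}

# World coordinates of every voxel centre along each grid axis, as three
# vectors (valid only for axis-aligned geometry); used by the phantom and
# the clipping code via outer expansion.
axis_world_coords <- function(geom) {
  if (max(abs(geom@directions - diag(3))) > 1e-9)
    orb_stop("orbvol_geometry_error",
             "axis-aligned (identity direction) geometry required here")
  lapply(1:3, function(a)
    geom@origin[a] + (seq_len(geom@shape[a]) - 1) * geom@spacing[a])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n <= 0)
    orb_stop("orbvol_degenerate_error", "zero-length direction vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Best-fit (least-squares) plane of a point ring: returns list(center, normal,
# e1, e2) with the normal oriented along `hint` when given.
best_fit_plane <- function(P, hint = NULL) {
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2L, ctr))
  nrm <- sv$v[, 3L]
  if (!is.null(hint) && sum(nrm * hint) < 0) nrm <- -nrm
  e1 <- sv$v[, 1L]
  e1 <- normalize3(e1 - sum(e1 * nrm) * nrm)
  e2 <- cross3(nrm, e1)
  list(center = ctr, normal = nrm, e1 = e1, e2 = e2)
}

# TRUE when the closed ring self-crosses after projection on its best-fit
# plane (non-adjacent segment pairs intersecting).
ring_self_crosses <- function(P) {
  pl <- best_fit_plane(P)
  rel <- sweep(P, 2L, pl$center)
  u <- cbind(rel %*% pl$e1, rel %*% pl$e2)
  n <- nrow(u)
  seg_from <- u
  seg_to <- u[c(2:n, 1L), , drop = FALSE]
  crosses <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1
    d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t1 <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    t2 <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t1 > 1e-9 && t1 < 1 - 1e-9 && t2 > 1e-9 && t2 < 1 - 1e-9
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next  # adjacent through the wrap
      if (crosses(seg_from[i, ], seg_to[i, ], seg_from[j, ], seg_to[j, ]))
        return(TRUE)
    }
  }
  FALSE
}

fmt_cc <- function(x) sprintf("%.2f cc", x)
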