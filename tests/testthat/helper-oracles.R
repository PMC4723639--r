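# Independent brute-force oracles, deliberately written with plain loops and
# exhaustive enumeration so they share no code path with the package.

# Flood-fill labelling by explicit queue over an integer offset table.
oracle_components <- function(values, connectivity = 26L) {
  d <- dim(values)
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    manh <- abs(dx) + abs(dy) + abs(dz)
    if (manh == 0) next
    if (connectivity == 6 && manh > 1) next
    if (connectivity == 18 && manh > 2) next
    offs[[length(offs) + 1L]] <- c(dx, dy, dz)
  }
  labels <- array(0L, d)
  nxt <- 0L
  stack <- integer(sum(values))
  for (start in which(values)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    top <- 1L
    stack[1L] <- start
    labels[start] <- nxt
    while (top > 0L) {
      cur <- stack[top]
      top <- top - 1L
      ijk <- arrayInd(cur, d)
      for (o in offs) {
        p <- ijk + o
        if (any(p < 1L) || any(p > d)) next
        lin <- p[1] + d[1] * (p[2] - 1L + d[2] * (p[3] - 1L))
        if (values[lin] && labels[lin] == 0L) {
          labels[lin] <- nxt
          top <- top + 1L
          stack[top] <- lin
        }
      }
    }
  }
  labels
}

oracle_largest_component <- function(values, connectivity = 26L) {
  labels <- oracle_components(values, connectivity)
  if (max(labels) == 0L) return(values & FALSE)
  sizes <- tabulate(labels[labels > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component containing the smallest linear voxel index
    firsts <- vapply(best, function(b) min(which(labels == b)), 0L)
    best <- best[which.min(firsts)]
  }
  labels == best
}

# Boundary voxels by explicit 6-neighbour check (edge of grid = outside).
oracle_boundary <- function(values) {
  d <- dim(values)
  out <- array(FALSE, d)
  for (lin in which(values)) {
    ijk <- arrayInd(lin, d)
    exposed <- FALSE
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      p <- ijk
      p[axis] <- p[axis] + s
      if (p[axis] < 1L || p[axis] > d[axis]) { exposed <- TRUE; break }
      if (!values[p[1], p[2], p[3]]) { exposed <- TRUE; break }
    }
    out[lin] <- exposed
  }
  out
}

# Exhaustive all-pairs nearest-boundary distances (mm) for every boundary
# voxel of `test_vals` against the boundary of `ref_vals`.
oracle_surface_distances <- function(test_vals, ref_vals, spacing) {
  tb <- which(oracle_boundary(test_vals))
  rb <- which(oracle_boundary(ref_vals))
  d <- dim(test_vals)
  ti <- arrayInd(tb, d)
  ri <- arrayInd(rb, d)
  mags <- numeric(length(tb))
  for (k in seq_along(tb)) {
    dx <- (ti[k, 1] - ri[, 1]) * spacing[1]
    dy <- (ti[k, 2] - ri[, 2]) * spacing[2]
    dz <- (ti[k, 3] - ri[, 3]) * spacing[3]
    mags[k] <- sqrt(min(dx^2 + dy^2 + dz^2))
  }
  sgn <- numeric(length(tb))
  ref_b <- oracle_boundary(ref_vals)
  for (k in seq_along(tb)) {
    sgn[k] <- if (ref_b[tb[k]]) 0 else if (ref_vals[tb[k]]) -1 else 1
  }
  list(index = tb, magnitude = mags, sign = sgn)
}

# ICC(A,1) from sums of squares computed by explicit loops.
oracle_icc_a1 <- function(tab) {
  n <- nrow(tab)
  k <- ncol(tab)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + tab[i, j]
  grand <- grand / (n * k)
  row_means <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in 1:k) s <- s + tab[i, j]
    row_means[i] <- s / k
  }
  col_means <- numeric(k)
  for (j in 1:k) {
    s <- 0
    for (i in 1:n) s <- s + tab[i, j]
    col_means[j] <- s / n
  }
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (row_means[i] - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (col_means[j] - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (tab[i, j] - row_means[i] - col_means[j] + grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Random blocky masks: unions of a few random boxes, occasionally inverted;
# produces both smooth and ragged boundaries.
random_mask <- function(dim3, n_boxes = 3L, p_invert = 0.1) {
  vals <- array(FALSE, dim3)
  for (b in seq_len(n_boxes)) {
    lo <- pmax(1L, sapply(dim3, function(n) sample.int(n, 1L)))
    hi <- pmin(dim3, lo + sapply(dim3, function(n) sample.int(max(2L, n %/% 2L), 1L)))
    vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  if (stats::runif(1) < p_invert) vals <- !vals
  vals
}
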