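test_that("centroid is the component-wise mean and translation-equivariant", {
  expect_equal(centroid(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(centroid(sq), c(0.5, 0.5, 0))
  set.seed(2)
  P <- matrix(stats::rnorm(15), 5, 3)
  shift <- c(3, -2, 7)
  expect_equal(centroid(P + rep(shift, each = 5)), centroid(P) + shift)
  expect_error(centroid(matrix(numeric(0), 0, 3)),
               class = "orbvol_degenerate_error")
})

test_that("fan surface has n triangles through the centroid with oriented normals", {
  ring <- square_ring(1)
  s <- buildFanSurface(ring, c(0, 0, 1))
  expect_equal(nrow(s@triangles), 4)
  expect_true(all(s@triangles[, 1] == 5))
  expect_equal(s@vertices[5, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(surfaceArea(s), 1.0)

  # all triangle normals point along the hint
  V <- s@vertices
  for (i in 1:4) {
    a <- V[s@triangles[i, 2], ] - V[s@triangles[i, 1], ]
    b <- V[s@triangles[i, 3], ] - V[s@triangles[i, 1], ]
    nrm <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
    expect_gt(sum(nrm * c(0, 0, 1)), 0)
  }

  # coplanar ring -> coplanar surface; n landmarks -> n triangles
  set.seed(4)
  n <- 9
  th <- sort(stats::runif(n, 0, 2 * pi))
  ring2 <- landmarkSet(cbind(10 * cos(th), 10 * sin(th), 5))
  s2 <- buildFanSurface(ring2, c(0, 0, -1))
  expect_equal(nrow(s2@triangles), n)
  expect_true(all(abs(s2@vertices[, 3] - 5) < 1e-12))
})

test_that("degenerate (collinear) fan triangles warn but are kept", {
  # two consecutive landmarks sit on one ray from the centroid (0,0,0), so
  # their fan triangle is collinear with the apex and has zero area
  ring <- landmarkSet(rbind(
    c(1, 1, 0), c(2, 2, 0), c(-1.5, 0.5, 0), c(-1.5, -3.5, 0)
  ))
  expect_warning(s <- buildFanSurface(ring, c(0, 0, 1)), "degenerate")
  expect_equal(nrow(s@triangles), 4)
})

test_that("landmark validation rejects short, close and self-crossing rings", {
  expect_error(landmarkSet(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))))
  expect_error(landmarkSet(rbind(c(0, 0, 0), c(0.05, 0, 0), c(1, 1, 0),
                                 c(0, 1, 0))))
  bowtie <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(landmarkSet(bowtie), "self-cross")
})

test_that("anterior clipping removes voxel centres on the hinted side", {
  # solid 10^3 cube at 0.5 mm; plane between the 5th and 6th voxel layers
  cube <- mask_from(array(TRUE, c(10, 10, 10)))
  ring <- landmarkSet(rbind(
    c(-5, -5, 2.5), c(10, -5, 2.5), c(10, 10, 2.5), c(-5, 10, 2.5)
  ))
  s <- buildFanSurface(ring, c(0, 0, 1))
  clipped <- clipAnterior(cube, s)
  expect_equal(voxelCount(clipped), 500)
  # retained voxels all below the plane
  kept <- which(clipped@values, arr.ind = TRUE)
  expect_true(all(kept[, 3] <= 5))
  # idempotent
  expect_identical(clipAnterior(clipped, s)@values, clipped@values)
  # surface entirely anterior to the mask leaves it unchanged
  ring_hi <- landmarkSet(rbind(
    c(-5, -5, 99), c(10, -5, 99), c(10, 10, 99), c(-5, 10, 99)
  ))
  s_hi <- buildFanSurface(ring_hi, c(0, 0, 1))
  expect_identical(clipAnterior(cube, s_hi)@values, cube@values)
  # empty in, empty out
  empty <- mask_from(array(FALSE, c(4, 4, 4)))
  expect_equal(voxelCount(clipAnterior(empty, s)), 0)
})

test_that("clipping conserves volume against the complementary half", {
  set.seed(9)
  m <- mask_from(random_mask(c(10, 10, 10)))
  ring <- landmarkSet(rbind(
    c(-9.2, -8.3, 1.3), c(8.7, -9.1, 1.7), c(9.3, 7.9, 2.2),
    c(-2.1, 9.4, 1.9), c(-8.8, 5.2, 1.6)
  ))
  s_up <- buildFanSurface(ring, c(0, 0, 1))
  s_dn <- buildFanSurface(ring, c(0, 0, -1))
  up <- clipAnterior(m, s_up)
  dn <- clipAnterior(m, s_dn)
  # each voxel is removed by exactly one of the two opposite clips
  # (strictly-on-plane centres are kept by both; none here)
  expect_equal(voxelCount(up) + voxelCount(dn), voxelCount(m))
  expect_equal(voxelCount(maskIntersect(up, dn)), 0)
})

test_that("planar-ring clipping equals a closed-form half-space test", {
  set.seed(14)
  m <- mask_from(random_mask(c(12, 12, 12)))
  n_lm <- 7
  th <- sort(stats::runif(n_lm, 0, 2 * pi))
  plane_z <- 2.6
  ring <- landmarkSet(cbind(3 + 8 * cos(th), 3 + 8 * sin(th), plane_z))
  s <- buildFanSurface(ring, c(0, 0, 1))
  got <- clipAnterior(m, s)
  idx <- which(m@values, arr.ind = TRUE)
  zc <- (idx[, 3] - 0.5) * 0.5
  want <- m@values
  want[m@values][zc > plane_z] <- FALSE
  expect_identical(got@values, want)
})

test_that("clipping is equivariant under joint translation of mask and landmarks", {
  case <- generatePhantom(small_phantom_spec(), hu = FALSE)
  s1 <- buildFanSurface(case@landmarks)
  v1 <- maskVolume(clipAnterior(case@truth_mask, s1))
  shift <- c(4.5, -3.25, 1.75)
  g <- case@truth_mask@geometry
  g2 <- voxelGeometry(g@shape, g@spacing, g@origin + shift, g@directions)
  m2 <- binaryMask(case@truth_mask@values, g2)
  lm2 <- landmarkSet(sweep(case@landmarks@points, 2, -shift))
  v2 <- maskVolume(clipAnterior(m2, buildFanSurface(lm2)))
  expect_equal(v1, v2)
})

test_that("ring resampling preserves arc length structure", {
  sq <- square_ring(10)  # perimeter 40
  r4 <- ringResample(sq, 10)
  expect_equal(nrow(r4@points), 4)
  expect_equal(r4@points[1, ], sq@points[1, ], ignore_attr = TRUE)

  # equally spaced ring resampled at its own spacing keeps the point count
  n <- 12
  th <- 2 * pi * (0:(n - 1)) / n
  circ <- landmarkSet(cbind(20 * cos(th), 20 * sin(th), 0))
  seg <- sqrt(sum((circ@points[2, ] - circ@points[1, ])^2))
  expect_equal(nrow(ringResample(circ, seg)@points), n)

  # fine resampling keeps the perimeter within 1%
  per <- function(P) {
    Pc <- rbind(P, P[1, ])
    sum(sqrt(rowSums(diff(Pc)^2)))
  }
  fine <- ringResample(circ, 3)
  expect_lt(abs(per(fine@points) - per(circ@points)) / per(circ@points),
            0.01)
  expect_error(ringResample(circ, -1), class = "orbvol_threshold_error")
})
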