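test_that("threshold masks use inclusive bone/air bounds", {
  flat <- vol_from(array(0, c(3, 3, 3)))
  expect_equal(voxelCount(thresholdMask(flat, lo = 400)), 0)
  expect_equal(voxelCount(thresholdMask(flat, hi = -600)), 0)

  v <- vol_from(array(c(-800, 0, 500), c(3, 1, 1)))
  bone <- thresholdMask(v, lo = 400)
  air <- thresholdMask(v, hi = -600)
  expect_equal(which(bone@values), 3L)
  expect_equal(which(air@values), 1L)

  # inclusivity at the exact threshold value
  v2 <- vol_from(array(c(400, -600, 0), c(3, 1, 1)))
  expect_true(thresholdMask(v2, lo = 400)@values[1, 1, 1])
  expect_true(thresholdMask(v2, hi = -600)@values[2, 1, 1])

  expect_error(thresholdMask(v, lo = 10, hi = -10),
               class = "orbvol_threshold_error")
  expect_error(thresholdMask(v), class = "orbvol_threshold_error")
})

test_that("bone, air and mid-range masks partition any volume", {
  set.seed(5)
  v <- vol_from(array(stats::runif(4^3, -1100, 3100), c(4, 4, 4)))
  bone <- thresholdMask(v, lo = 400)
  air <- thresholdMask(v, hi = -600)
  mid <- thresholdMask(v, lo = -600 + 1e-9, hi = 400 - 1e-9)
  expect_equal(voxelCount(maskIntersect(bone, air)), 0)
  expect_equal(voxelCount(maskIntersect(bone, mid)), 0)
  expect_equal(voxelCount(maskIntersect(air, mid)), 0)
  expect_equal(voxelCount(maskUnion(maskUnion(bone, air), mid)), 64)
})

test_that("mask algebra matches Boolean laws and exact counting", {
  set.seed(11)
  for (rep in 1:20) {
    a <- mask_from(array(stats::runif(27) < 0.5, c(3, 3, 3)))
    b <- mask_from(array(stats::runif(27) < 0.5, c(3, 3, 3)))
    expect_identical(maskSubtract(a, b)@values, a@values & !b@values)
    expect_identical(maskUnion(a, b)@values, maskUnion(b, a)@values)
    expect_identical(maskIntersect(a, b)@values, maskIntersect(b, a)@values)
    expect_identical(maskUnion(a, a)@values, a@values)
    expect_identical(maskIntersect(a, a)@values, a@values)
    expect_equal(voxelCount(maskSubtract(a, b)),
                 voxelCount(a) - voxelCount(maskIntersect(a, b)))
  }
  a <- mask_from(array(TRUE, c(2, 2, 2)))
  expect_equal(voxelCount(maskSubtract(a, a)), 0)
  empty <- mask_from(array(FALSE, c(2, 2, 2)))
  expect_identical(maskSubtract(a, empty)@values, a@values)
  # disjoint additivity
  d1 <- array(FALSE, c(4, 2, 2)); d1[1:2, , ] <- TRUE
  d2 <- array(FALSE, c(4, 2, 2)); d2[3:4, , ] <- TRUE
  expect_equal(voxelCount(maskUnion(mask_from(d1), mask_from(d2))),
               voxelCount(mask_from(d1)) + voxelCount(mask_from(d2)))
  bad <- binaryMask(array(FALSE, c(2, 2, 2)),
                    voxelGeometry(c(2, 2, 2), spacing = c(1, 1, 1)))
  expect_error(maskSubtract(a, bad), class = "orbvol_geometry_error")
})

test_that("mask volume follows voxel count times voxel volume in cc", {
  expect_equal(maskVolume(mask_from(array(FALSE, c(2, 2, 2)))), 0)
  cube <- mask_from(array(TRUE, c(20, 20, 20)))  # 8000 voxels at 0.5 mm
  expect_equal(maskVolume(cube), 1.0)
  m <- binaryMask(array(c(rep(TRUE, 100), rep(FALSE, 150)), c(5, 5, 10)),
                  voxelGeometry(c(5, 5, 10), spacing = c(0.4, 0.4, 2.0)))
  expect_equal(maskVolume(m), 100 * 0.4 * 0.4 * 2.0 / 1000)
  expect_equal(maskVolume(m), 0.032)
})

test_that("mask volume is invariant under axis permutation with permuted spacing", {
  set.seed(21)
  vals <- array(stats::runif(3 * 4 * 5) < 0.4, c(3, 4, 5))
  sp <- c(0.4, 0.5, 2.0)
  v1 <- maskVolume(binaryMask(vals, voxelGeometry(dim(vals), spacing = sp)))
  perm <- c(3, 1, 2)
  vals_p <- aperm(vals, perm)
  v2 <- maskVolume(binaryMask(vals_p,
                              voxelGeometry(dim(vals_p), spacing = sp[perm])))
  expect_equal(v1, v2)
})

test_that("largest component keeps the biggest region deterministically", {
  one <- array(FALSE, c(6, 6, 6)); one[2:4, 2:4, 2:4] <- TRUE
  m <- mask_from(one)
  expect_identical(largestComponent(m)@values, one)

  two <- array(FALSE, c(8, 4, 4))
  two[1:2, 1:2, 1:2] <- TRUE        # 8 voxels... adjust: make 10 vs 3
  two[1:2, 1:2, 3] <- TRUE          # +4 -> 12 voxels
  two[7:8, 3, 3] <- TRUE            # 2 voxels
  two[8, 4, 4] <- TRUE              # diagonal neighbour of (8,3,3) under 26
  got <- largestComponent(mask_from(two), 26L)
  expect_equal(sum(got@values), 12)
  expect_true(all(which(got@values) %in% which(two)))

  # diagonal pair: separate under 6-connectivity, joined under 26
  diag2 <- array(FALSE, c(3, 3, 3))
  diag2[1, 1, 1] <- TRUE; diag2[2, 2, 2] <- TRUE
  expect_equal(sum(largestComponent(mask_from(diag2), 26L)@values), 2)
  expect_equal(sum(largestComponent(mask_from(diag2), 6L)@values), 1)
  # 6-connectivity tie: the component holding the smaller voxel index wins
  expect_equal(which(largestComponent(mask_from(diag2), 6L)@values), 1L)

  empty <- mask_from(array(FALSE, c(3, 3, 3)))
  expect_equal(voxelCount(largestComponent(empty)), 0)
})

test_that("largest component agrees with a brute-force flood fill", {
  set.seed(33)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:15) {
      vals <- random_mask(c(6, 6, 6))
      got <- largestComponent(mask_from(vals), conn)@values
      want <- oracle_largest_component(vals, conn)
      expect_identical(got, want)
    }
  }
})

test_that("morphological closing spans gaps, is extensive and idempotent", {
  m <- mask_from(array(stats::runif(5^3) < 0.3, c(5, 5, 5)))
  expect_identical(morphologicalClose(m, 0)@values, m@values)

  # two voxels one voxel apart along a line: radius of one voxel spacing
  # bridges the gap (the eroding ball cannot fit into the notch)
  gap <- array(FALSE, c(7, 1, 1))
  gap[3, 1, 1] <- TRUE; gap[5, 1, 1] <- TRUE
  closed <- morphologicalClose(mask_from(gap), 0.5)  # 1 voxel at 0.5 mm
  expect_true(closed@values[4, 1, 1])
  expect_true(all(closed@values[which(gap)]))
  expect_equal(sum(closed@values), 3)

  set.seed(7)
  for (rep in 1:5) {
    m <- mask_from(array(stats::runif(6^3) < 0.25, c(6, 6, 6)))
    c1 <- morphologicalClose(m, 1.1)
    expect_true(all(c1@values | !m@values))  # extensive
    expect_identical(morphologicalClose(c1, 1.1)@values, c1@values)
  }
})

test_that("closing radius is physical: behaviour tracks mm, not voxels", {
  gap <- array(FALSE, c(7, 1, 1))
  gap[3, 1, 1] <- TRUE; gap[5, 1, 1] <- TRUE
  # same geometry at 1 mm spacing: the 2 mm-apart voxels need radius >= 1 mm
  coarse <- binaryMask(gap, voxelGeometry(dim(gap), spacing = c(1, 1, 1)))
  expect_false(morphologicalClose(coarse, 0.5)@values[4, 1, 1])
  expect_true(morphologicalClose(coarse, 1.0)@values[4, 1, 1])
})

test_that("HU volume construction validates shape and warns on implausible values", {
  expect_warning(vol_from(array(5000, c(2, 2, 2))), "plausible")
  expect_error(huVolume(array(0, c(2, 2, 2)), voxelGeometry(c(3, 3, 3))))
  expect_silent(vol_from(array(c(-1100, 3100), c(2, 1, 1))))
})
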