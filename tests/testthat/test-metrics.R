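test_that("Dice coefficient matches voxel counting and its conventions", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, 1:4, 1] <- TRUE        # 8 voxels
  b <- array(FALSE, c(4, 4, 2)); b[1:2, 3:4, 1] <- TRUE        # 4 overlap
  b[3:4, 1:2, 2] <- TRUE                                       # +4 -> 8
  ma <- mask_from(a); mb <- mask_from(b)
  expect_equal(diceCoefficient(ma, mb), 0.5)
  expect_equal(diceCoefficient(ma, mb), diceCoefficient(mb, ma))
  expect_equal(diceCoefficient(ma, ma), 1.0)
  disj <- mask_from(array(FALSE, c(4, 4, 2)))
  disj@values[4, 4, 2] <- TRUE
  expect_equal(diceCoefficient(ma, disj), 0.0)
  e <- mask_from(array(FALSE, c(4, 4, 2)))
  expect_equal(diceCoefficient(e, e), 1.0)   # empty-vs-empty convention
})

test_that("surface distances vanish for identical masks and track a face shift", {
  cube <- array(FALSE, c(12, 12, 12)); cube[4:9, 4:9, 4:9] <- TRUE
  m <- mask_from(cube)
  dm <- surfaceDistanceMap(m, m)
  expect_true(all(dm@signed_distances == 0))
  expect_equal(dm@summary$mean_signed_mm, 0)
  expect_equal(dm@summary$p95_abs_mm, 0)

  # one face pushed outward by one 0.5 mm voxel layer
  shifted <- cube; shifted[10, 4:9, 4:9] <- TRUE
  ms <- mask_from(shifted)
  dms <- surfaceDistanceMap(ms, m)
  orc <- oracle_surface_distances(shifted, cube, c(0.5, 0.5, 0.5))
  expect_equal(sort(abs(dms@signed_distances)), sort(orc$magnitude))
  # the shifted face's interior points sit 0.5 mm outside the reference
  face_pts <- dms@points[, 1] > 4.6 & abs(dms@signed_distances) > 0
  expect_true(any(dms@signed_distances == 0.5))
  expect_equal(dms@summary$mean_signed_mm, mean(orc$sign * orc$magnitude))
})

test_that("swapping a strictly nested pair flips every non-zero sign", {
  outer <- array(FALSE, c(14, 14, 14)); outer[3:12, 3:12, 3:12] <- TRUE
  inner <- array(FALSE, c(14, 14, 14)); inner[6:9, 6:9, 6:9] <- TRUE
  mo <- mask_from(outer); mi <- mask_from(inner)
  d_oi <- surfaceDistanceMap(mo, mi)   # test boundary outside ref -> +
  d_io <- surfaceDistanceMap(mi, mo)   # test boundary inside ref -> -
  expect_true(all(d_oi@signed_distances > 0))
  expect_true(all(d_io@signed_distances < 0))
  expect_error(surfaceDistanceMap(mo, mask_from(array(FALSE, c(14, 14, 14)))),
               class = "orbvol_degenerate_error")
})

test_that("p95 distance grows monotonically under outward dilation", {
  ref <- array(FALSE, c(16, 16, 16)); ref[6:11, 6:11, 6:11] <- TRUE
  mref <- mask_from(ref)
  p95 <- sapply(c(0, 0.5, 1.0, 1.5), function(r) {
    t <- orbvol:::mask_dilate(mref, r)
    surfaceDistanceMap(t, mref)@summary$p95_abs_mm
  })
  expect_true(all(diff(p95) >= 0))
  expect_gt(p95[4], p95[1])
})

test_that("ICC of duplicated and offset raters follows absolute agreement", {
  vols <- c(25.1, 28.4, 30.2, 27.7, 31.5, 29.0)
  same <- cbind(vols, vols)
  r <- iccAgreement(same)
  expect_equal(r@icc, 1.0)
  expect_equal(r@model_label,
               "two-way random, absolute agreement, single measure")
  # a large constant offset with tiny subject variance drives ICC toward 0
  off <- cbind(vols, vols + 100)
  expect_lt(iccAgreement(off)@icc, 0.05)
  expect_error(iccAgreement(cbind(rep(1, 4), rep(1, 4))),
               class = "orbvol_degenerate_error")
  expect_error(iccAgreement(matrix(1:4, 4, 1)),
               class = "orbvol_degenerate_error")
})

test_that("ICC matches the explicit sums-of-squares oracle to 1e-10", {
  tab <- cbind(c(27.4, 30.1, 25.8, 29.3, 31.0, 28.2),
               c(27.9, 29.8, 26.4, 29.1, 31.6, 28.0))
  got <- iccAgreement(tab)
  expect_equal(got@icc, oracle_icc_a1(tab), tolerance = 1e-10)
  expect_lte(got@ci_low, got@icc)
  expect_gte(got@ci_high, got@icc)

  set.seed(41)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    k <- sample(2:4, 1)
    tab <- matrix(stats::rnorm(n * k, 30, 3), n, k) +
      stats::rnorm(n, 0, 2)   # subject effects
    expect_equal(iccAgreement(tab)@icc, oracle_icc_a1(tab),
                 tolerance = 1e-10)
  }
})

test_that("paired t statistic matches hand arithmetic and is antisymmetric", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)     # d = (1, 2, 3)
  got <- pairedT(x, y)
  expect_equal(got$t, 2 * sqrt(3))
  expect_equal(got$df, 2)
  swapped <- pairedT(y, x)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  expect_error(pairedT(x, x + 5), class = "orbvol_degenerate_error")
  expect_error(pairedT(1, 2), class = "orbvol_degenerate_error")
})

test_that("agreement reports are internally consistent", {
  cube <- array(FALSE, c(10, 10, 10)); cube[3:8, 3:8, 3:8] <- TRUE
  m <- mask_from(cube)
  rep0 <- compareMasks(m, m)
  expect_equal(rep0@mean_diff_cc, 0)
  expect_equal(rep0@dice, 1)
  expect_true(all(rep0@distance_map@signed_distances == 0))
  expect_true(is.na(rep0@t_statistic))

  bigger <- orbvol:::mask_dilate(m, 0.5)
  rep1 <- compareMasks(bigger, m,
                       cohort_test_cc = c(29.1, 30.4, 28.8, 31.0),
                       cohort_ref_cc = c(28.8, 30.1, 28.9, 30.2))
  expect_equal(rep1@mean_diff_cc,
               rep1@volume_test_cc - rep1@volume_ref_cc)
  expect_gt(rep1@mean_diff_cc, 0)
  expect_false(is.na(rep1@p_value))
})
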