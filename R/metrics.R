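#' @include AllClasses.R utils.R mask-ops.R
NULL

#' Dice overlap coefficient
#'
#' \code{2|A intersect B| / (|A| + |B|)}. Two empty masks are defined to
#' agree perfectly (Dice 1), by convention.
#'
#' @param a,b \linkS4class{BinaryMask}s sharing one geometry.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  check_same_geometry(a, b)
  na <- sum(a@values)
  nb <- sum(b@values)
  if (na + nb == 0L) return(1.0)
  2 * sum(a@values & b@values) / (na + nb)
}

# Boundary voxels: mask voxels with at least one 6-connected face neighbour
# outside the mask (voxels on the grid edge count as exposed).
boundary_voxels <- function(values) {
  d <- dim(values)
  out <- array(FALSE, d)
  pad_shift <- function(axis, dir) {
    shifted <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (dir > 0) {
      idx_dst[[axis]] <- 2:d[axis]
      idx_src[[axis]] <- 1:(d[axis] - 1)
    } else {
      idx_dst[[axis]] <- 1:(d[axis] - 1)
      idx_src[[axis]] <- 2:d[axis]
    }
    shifted[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      values[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    shifted
  }
  exposed <- array(FALSE, d)
  for (axis in 1:3) for (dir in c(-1, 1)) {
    exposed <- exposed | !pad_shift(axis, dir)
  }
  values & exposed
}

#' Signed surface distance map
#'
#' Samples the boundary of the test mask (voxels with a face neighbour
#' outside the mask) at voxel centres and measures, per point, the Euclidean
#' distance in mm (spacing-aware) to the nearest reference boundary voxel
#' centre. The sign encodes containment: +1 when the test boundary point
#' lies outside the reference, -1 inside, 0 on a reference boundary voxel.
#' Distances are one-directional (test boundary to reference surface),
#' matching "method versus gold standard" comparisons; set
#' \code{symmetric = TRUE} to pool both directions' magnitudes into the
#' summary. Summaries: mean signed distance, mean absolute distance, and the
#' 95th percentile of absolute distances (linear interpolation between order
#' statistics, quantile type 7).
#'
#' @param test,ref non-empty \linkS4class{BinaryMask}s sharing one geometry.
#' @param symmetric also include ref-to-test magnitudes in the summary
#'   statistics (the point set and signed distances remain test-to-ref).
#' @return A \linkS4class{DistanceMap}.
#' @export
surfaceDistanceMap <- function(test, ref, symmetric = FALSE) {
  check_same_geometry(test, ref)
  if (!any(test@values) || !any(ref@values))
    orb_stop("orbvol_degenerate_error",
             "surface distances are undefined for empty masks")
  tb <- boundary_voxels(test@values)
  rb <- boundary_voxels(ref@values)
  d2 <- cpp_edt_sq(as.logical(rb), dim(rb), ref@geometry@spacing)
  idx <- which(tb)
  mag <- sqrt(d2[idx])
  sgn <- ifelse(rb[idx], 0, ifelse(ref@values[idx], -1, 1))
  signed <- sgn * mag
  signed[sgn == 0] <- 0
  pts <- voxel_to_world(test@geometry, arrayInd(idx, dim(tb)) - 1)
  colnames(pts) <- c("x", "y", "z")
  abs_all <- abs(signed)
  if (symmetric) {
    d2r <- cpp_edt_sq(as.logical(tb), dim(tb), test@geometry@spacing)
    abs_all <- c(abs_all, sqrt(d2r[which(rb)]))
  }
  summ <- list(
    mean_signed_mm = mean(signed),
    mean_abs_mm = mean(abs_all),
    p95_abs_mm = as.numeric(stats::quantile(abs_all, 0.95, type = 7,
                                            names = FALSE)),
    n_points = length(signed),
    direction = if (symmetric) "symmetric" else "test_to_reference",
    percentile_rule = "linear interpolation between order statistics (type 7)"
  )
  new("DistanceMap", points = pts, signed_distances = signed, summary = summ)
}

#' Intraclass correlation for absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (McGraw--Wong ICC(A,1)) of a complete subjects x raters table
#' of volumes, computed from the two-way ANOVA mean squares, with the
#' standard F-based 95\% confidence interval. Absolute agreement penalises
#' systematic rater offsets, the appropriate choice for interchangeable
#' human raters; the model label is carried in the result so the choice is
#' auditable.
#'
#' @param ratings numeric matrix, rows = subjects (>= 2), columns = raters
#'   (>= 2), complete.
#' @param conf_level confidence level (default 0.95).
#' @return An \linkS4class{ICCResult}.
#' @export
iccAgreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L || any(!is.finite(ratings)))
    orb_stop("orbvol_degenerate_error",
             "a complete table with >= 2 subjects and >= 2 raters is required")
  if (max(ratings) - min(ratings) == 0)
    orb_stop("orbvol_degenerate_error",
             "all ratings identical: zero total variance")
  df <- data.frame(
    y = as.numeric(ratings),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  # only the mean squares are consumed; anova()'s F tests (which warn on a
  # perfect fit) are not used
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ subject + rater, data = df))[["Mean Sq"]])
  msr <- ms[1L]  # rows / subjects
  msc <- ms[2L]  # columns / raters
  mse <- ms[3L]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # F-based interval (McGraw & Wong 1996, ICC(A,1)); perfect agreement
  # (MSE = 0) collapses it to a point
  alpha <- 1 - conf_level
  lower <- upper <- icc
  if (mse > 0 && icc < 1) {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    if (is.finite(v) && v > 0) {
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
      if (!is.finite(lower)) lower <- icc
      if (!is.finite(upper)) upper <- icc
    }
  }
  new("ICCResult", icc = icc, ci_low = min(lower, icc),
      ci_high = max(upper, icc),
      model_label = "two-way random, absolute agreement, single measure",
      n_subjects = as.integer(n), n_raters = as.integer(k),
      mean_squares = c(MSR = msr, MSC = msc, MSE = mse))
}

#' Paired Student's t test
#'
#' Two-sided paired t test on matched samples:
#' \code{t = mean(d) / (sd(d) / sqrt(n))} on differences \code{d = x - y},
#' with \code{n - 1} degrees of freedom. Zero-variance differences are a
#' degenerate-data error.
#'
#' @param x,y paired numeric samples of equal length n >= 2.
#' @return list with \code{t}, \code{df} and two-sided \code{p}.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    orb_stop("orbvol_degenerate_error",
             "paired samples of equal length >= 2 are required")
  d <- x - y
  if (stats::sd(d) == 0)
    orb_stop("orbvol_degenerate_error",
             "zero-variance paired differences: t statistic undefined")
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Full agreement report for a mask pair
#'
#' Assembles volumes, volume difference, Dice and the signed surface
#' distance summary into one report, the presentation used to compare a
#' segmentation method against a gold standard. When cohort volume vectors
#' are supplied, a paired t test over them fills the t statistic and p
#' value; for a single mask pair they are NA.
#'
#' @param test,ref \linkS4class{BinaryMask}s sharing one geometry.
#' @param cohort_test_cc,cohort_ref_cc optional paired volume vectors (cc)
#'   across a case cohort for the t test.
#' @return An \linkS4class{AgreementReport}.
#' @export
compareMasks <- function(test, ref, cohort_test_cc = NULL,
                         cohort_ref_cc = NULL) {
  check_same_geometry(test, ref)
  dm <- surfaceDistanceMap(test, ref)
  tt <- list(t = NA_real_, p = NA_real_)
  if (!is.null(cohort_test_cc) && !is.null(cohort_ref_cc))
    tt <- pairedT(cohort_test_cc, cohort_ref_cc)
  new("AgreementReport",
      volume_test_cc = maskVolume(test), volume_ref_cc = maskVolume(ref),
      mean_diff_cc = maskVolume(test) - maskVolume(ref),
      dice = diceCoefficient(test, ref), distance_map = dm,
      t_statistic = tt$t, p_value = tt$p)
}
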