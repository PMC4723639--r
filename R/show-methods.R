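#' @include AllClasses.R mask-ops.R
NULL

setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (LPS mm): %.2f, %.2f, %.2f\n",
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "HUVolume", function(object) {
  cat("HUVolume (Hounsfield units)\n")
  show(object@geometry)
  cat(sprintf("  HU range: [%.0f, %.0f]\n", min(object@values),
              max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d voxels selected, %s\n",
              sum(object@values), fmt_cc(maskVolume(object))))
  show(object@geometry)
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet '%s': %d rim points\n", object@label,
              nrow(object@points)))
})

setMethod("show", "FanSurface", function(object) {
  cat(sprintf("FanSurface: %d triangles over %d rim landmarks, area %.1f mm^2\n",
              nrow(object@triangles), nrow(object@vertices) - 1L,
              surfaceArea(object)))
})

setMethod("show", "OrbitalVolumeResult", function(object) {
  cat("OrbitalVolumeResult\n")
  for (nm in names(object@stage_volumes_cc))
    cat(sprintf("  %-9s %s\n", nm, fmt_cc(object@stage_volumes_cc[[nm]])))
  cat(sprintf("  orbital volume: %s\n", fmt_cc(object@volume_cc)))
})

setMethod("show", "DistanceMap", function(object) {
  s <- object@summary
  cat(sprintf("DistanceMap: %d boundary points (%s)\n", s$n_points,
              s$direction))
  cat(sprintf("  mean signed %.3f mm, mean |d| %.3f mm, p95 |d| %.3f mm\n",
              s$mean_signed_mm, s$mean_abs_mm, s$p95_abs_mm))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC (%s)\n", object@model_label))
  cat(sprintf("  %.4f, 95%% CI [%.4f, %.4f]; %d subjects x %d raters\n",
              object@icc, object@ci_low, object@ci_high,
              object@n_subjects, object@n_raters))
})

setMethod("show", "AgreementReport", function(object) {
  cat("AgreementReport\n")
  cat(sprintf("  volumes: test %s, ref %s, diff %s\n",
              fmt_cc(object@volume_test_cc), fmt_cc(object@volume_ref_cc),
              fmt_cc(object@mean_diff_cc)))
  cat(sprintf("  dice %.4f; mean signed distance %.3f mm, p95 |d| %.3f mm\n",
              object@dice, object@distance_map@summary$mean_signed_mm,
              object@distance_map@summary$p95_abs_mm))
  if (!is.na(object@t_statistic))
    cat(sprintf("  paired t = %.3f, p = %.4g\n", object@t_statistic,
                object@p_value))
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase: analytic cavity volume %s (label %s)\n",
              fmt_cc(object@analytic_volume_cc),
              fmt_cc(maskVolume(object@truth_mask))))
  show(object@volume@geometry)
})
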