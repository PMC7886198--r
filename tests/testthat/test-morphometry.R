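rebuild_masks <- function(spec, timepoint = "day1", seed = 11L, noiseless = FALSE) {
  lv <- build_label_volume(spec, timepoint)
  tissues <- default_tissues()
  if (noiseless) for (nm in names(tissues)) tissues[[nm]]$t2_sd <- 0
  t2 <- simulate_t2(lv, tissues, seed = seed)
  hemi <- hemisphere_masks(spec$grid_shape, spec$voxel_size)
  gray_contra <- label_mask(unclass(hemi$contra) &
                              array(lv$labels == 1L, dim(lv$labels)),
                            spec$voxel_size, "contra_gray")
  list(lv = lv, t2 = t2, hemi = hemi, gray_contra = gray_contra)
}

test_that("mean + 2 SD thresholding recovers a planted hyperintense lesion", {
  spec <- small_spec(lesion_radius = c(0.9, 0.6, 0.4), snr = 30)
  fx <- rebuild_masks(spec)
  expect_message(segment_lesion(fx$t2, fx$gray_contra, fx$hemi$ipsi), "threshold")
  les <- suppressMessages(segment_lesion(fx$t2, fx$gray_contra, fx$hemi$ipsi))
  expect_equal(attr(les, "threshold"), 110, tolerance = 0.02)
  planted <- unclass(fx$lv$masks$lesion)
  expect_gt(mean(les[planted]), 0.99)       # lesion N(130,5) vs threshold ~110: Phi(4)
  expect_true(all(les[!unclass(fx$hemi$ipsi)] == FALSE))  # subset of ipsi hemisphere
})

test_that("lesion-free segmentation false positives sit at the Gaussian tail rate", {
  spec <- small_spec(lesion_radius = c(0, 0, 0))
  fx <- rebuild_masks(spec, seed = 23L)
  gray_ipsi <- label_mask(unclass(fx$hemi$ipsi) &
                            array(fx$lv$labels == 1L, dim(fx$lv$labels)),
                          spec$voxel_size, "ipsi_gray")
  les <- suppressMessages(segment_lesion(fx$t2, fx$gray_contra, gray_ipsi))
  rate <- sum(les) / sum(gray_ipsi)
  expect_gt(rate, 0.005); expect_lt(rate, 0.05)  # coarse here; calibrated bounds in acceptance
})

test_that("noiseless piecewise-constant segmentation equals the planted mask exactly", {
  spec <- small_spec(lesion_radius = c(0.9, 0.6, 0.4))
  fx <- rebuild_masks(spec, noiseless = TRUE)
  ipsi_parenchyma <- label_mask(unclass(fx$hemi$ipsi) &
                                  array(fx$lv$labels != 3L, dim(fx$lv$labels)),
                                spec$voxel_size, "ipsi_no_csf")
  les <- suppressWarnings(suppressMessages(
    segment_lesion(fx$t2, fx$gray_contra, ipsi_parenchyma)))
  expect_identical(unclass(les)[, , ], unclass(fx$lv$masks$lesion)[, , ])
})

test_that("zero-SD reference warns and falls back to the mean", {
  spec <- small_spec(lesion_radius = c(0.9, 0.6, 0.4))
  fx <- rebuild_masks(spec, noiseless = TRUE)
  expect_warning(suppressMessages(segment_lesion(fx$t2, fx$gray_contra, fx$hemi$ipsi)),
                 "zero intensity SD")
  expect_error(suppressMessages(
    segment_lesion(fx$t2, label_mask(array(FALSE, spec$grid_shape), spec$voxel_size),
                   fx$hemi$ipsi)), "empty contralateral")
})

test_that("raising the SD multiplier never enlarges the lesion mask", {
  spec <- small_spec(lesion_radius = c(0.9, 0.6, 0.4), snr = 30)
  fx <- rebuild_masks(spec)
  m2 <- suppressMessages(segment_lesion(fx$t2, fx$gray_contra, fx$hemi$ipsi, k = 2))
  m3 <- suppressMessages(segment_lesion(fx$t2, fx$gray_contra, fx$hemi$ipsi, k = 3))
  expect_true(all(!m3 | m2))    # m3 subset of m2
  expect_lte(sum(m3), sum(m2))
})

test_that("noiseless ventricular volumetry is exact and scaling is recovered", {
  # default grid: the ventricles span enough voxels that discretization
  # error stays well under the 10% band on the 1.5x volume scaling
  spec <- phantom_spec(lesion_radius = c(0, 0, 0),
                       ventricle_scale = c(1, 1.2, 1.5))
  fx1 <- rebuild_masks(spec, "day1", noiseless = TRUE)
  v1 <- measure_ventricles(fx1$t2, fx1$lv$masks$csf, 5:12, fx1$gray_contra)
  expect_equal(as.numeric(v1), mask_volume(fx1$lv$masks$csf))
  fx3 <- rebuild_masks(spec, "wk5", noiseless = TRUE)
  v3 <- measure_ventricles(fx3$t2, fx3$lv$masks$csf, 5:12, fx3$gray_contra)
  expect_equal(as.numeric(v3) / as.numeric(v1), 1.5, tolerance = 0.10)
  empty <- label_mask(array(FALSE, spec$grid_shape), spec$voxel_size)
  expect_equal(as.numeric(measure_ventricles(fx1$t2, empty, 5:12, fx1$gray_contra)), 0)
  expect_error(measure_ventricles(fx1$t2, fx1$lv$masks$csf, 12:19, fx1$gray_contra),
               "slice_range")
})

test_that("day-1 normalization behaves and guards division by zero", {
  out <- normalize_series(c(50, 30, 20), c("day1", "wk2", "wk5"))
  expect_equal(out$normalized, c(1.0, 0.6, 0.4))
  expect_equal(normalize_series(c(7, 7, 7))$normalized, c(1, 1, 1))
  expect_error(normalize_series(c(0, 3, 2)), "zero")
})
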