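test_that("lesion-free label volumes are exact mirror images", {
  spec <- small_spec(lesion_radius = c(0, 0, 0))
  lv <- build_label_volume(spec, "day1")
  flipped <- lv$labels[rev(seq_len(dim(lv$labels)[1])), , ]
  expect_identical(lv$labels, flipped)
})

test_that("tissue masks are disjoint and cover the grid", {
  lv <- build_label_volume(small_spec(), "day1")
  tissue <- c("background", "gray", "white", "csf", "lesion")
  total <- Reduce(`+`, lapply(lv$masks[tissue], function(m) array(as.integer(m), dim(m))))
  expect_true(all(total == 1L))
})

test_that("lesion mask shrinks monotonically with the planted radii", {
  spec <- small_spec(lesion_radius = c(0.9, 0.6, 0.4))
  counts <- vapply(spec$timepoints,
                   function(tp) sum(build_label_volume(spec, tp)$masks$lesion),
                   numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("planted sphere volume matches the analytic value within 10%", {
  spec <- phantom_spec(lesion_radius = c(2.0, 1.2, 0.8))  # default grid
  lv <- build_label_volume(spec, "day1")
  analytic <- 4 / 3 * pi * 2.0^3
  expect_lt(abs(mask_volume(lv$masks$lesion) - analytic) / analytic, 0.10)
})

test_that("oversized or midline-crossing lesions are rejected with a clear message", {
  expect_error(build_label_volume(small_spec(lesion_radius = c(1.3, 1.3, 1.3)), "day1"),
               "midsagittal|hemisphere")
  expect_error(phantom_spec(lesion_radius = c(0.5, 0.8, 0.9)), "non-increasing")
  expect_error(phantom_spec(grid_shape = c(33, 32, 8)), "even")
})

test_that("noiseless DWI signal matches the closed-form tensor attenuation", {
  # isotropic lambda = 1e-3: S/S0 = exp(-1) for every b=1000 direction
  spec <- small_spec(lesion_radius = c(0, 0, 0))
  lv <- build_label_volume(spec, "day1")
  tissues <- default_tissues()
  tissues$gray$eigenvalues <- c(1, 1, 1) * 1e-3
  dwi <- simulate_dwi(lv, tissues, gradient_scheme(), snr = Inf, s0 = 1000)
  vox <- which(array(lv$labels == 1L, dim(lv$labels)), arr.ind = TRUE)[1, ]
  sig <- dwi$data[vox[1], vox[2], vox[3], ]
  expect_equal(sig[1], 1000)
  expect_equal(sig[-1], rep(1000 * exp(-1), 30), tolerance = 1e-12)

  # prolate (1.7, .2, .2)e-3 along x with g = x-hat: S/S0 = exp(-1.7)
  sch <- validate_scheme(structure(list(
    bvals = c(0, rep(1000, 6)),
    bvecs = cbind(c(0, 0, 0), diag(3),
                  matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1) / sqrt(2), 3))),
    class = "gradient_scheme"))
  dwi2 <- simulate_dwi(lv, default_tissues(), sch, snr = Inf, s0 = 1000)
  wvox <- which(array(lv$labels == 2L, dim(lv$labels)), arr.ind = TRUE)[1, ]
  sw <- dwi2$data[wvox[1], wvox[2], wvox[3], ]
  expect_equal(sw[2] / sw[1], exp(-1.7), tolerance = 1e-12)  # g = x
  expect_equal(sw[3] / sw[1], exp(-0.2), tolerance = 1e-12)  # g = y
})

test_that("simulation errors are explicit", {
  spec <- small_spec()
  lv <- build_label_volume(spec, "day1")
  expect_error(simulate_dwi(lv, default_tissues(), gradient_scheme(), snr = 0),
               "snr")
  tis <- default_tissues(); tis$white <- NULL
  expect_error(simulate_dwi(lv, tis, gradient_scheme(), snr = Inf),
               "missing tissue model.*white")
  tis2 <- default_tissues(); tis2$gray$t2_sd <- -1
  expect_error(simulate_t2(lv, tis2), "negative")
})

test_that("same seed gives bit-identical volumes, different seed does not", {
  spec <- small_spec(snr = 20)
  lv <- build_label_volume(spec, "day1")
  a <- simulate_dwi(lv, default_tissues(), gradient_scheme(), snr = 20, seed = 9L)
  b <- simulate_dwi(lv, default_tissues(), gradient_scheme(), snr = 20, seed = 9L)
  c <- simulate_dwi(lv, default_tissues(), gradient_scheme(), snr = 20, seed = 10L)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  t1 <- simulate_t2(lv, default_tissues(), seed = 4L)
  t2 <- simulate_t2(lv, default_tissues(), seed = 4L)
  expect_identical(t1, t2)
})

test_that("T2 forward model plants a detectable hyperintense lesion", {
  spec <- small_spec(lesion_radius = c(0.9, 0.6, 0.4), snr = 30)
  lv <- build_label_volume(spec, "day1")
  t2 <- simulate_t2(lv, default_tissues(), seed = 11L)
  lesioned <- t2[unclass(lv$masks$lesion)]
  # lesion N(130, 5) exceeds 110 with probability Phi(4) ~ 0.99997
  expect_gt(mean(lesioned > 110), 0.999)
  tis0 <- default_tissues()
  for (nm in names(tis0)) tis0[[nm]]$t2_sd <- 0
  flat <- simulate_t2(lv, tis0, seed = 1L)
  expect_identical(sort(unique(as.vector(flat))),
                   sort(unique(c(0, 90, 100, 130, 300))))
})

test_that("gradient scheme invariants are enforced", {
  sch <- gradient_scheme()
  expect_length(sch$bvals, 31L)
  nz <- sch$bvals > 0
  expect_equal(colSums(sch$bvecs[, nz]^2), rep(1, 30), tolerance = 1e-12)
  expect_error(gradient_scheme(n_dirs = 5), "at least 6")
  bad <- structure(list(bvals = c(0, rep(1000, 6)),
                        bvecs = cbind(0, matrix(rep(c(1, 0, 0), 6), 3))),
                   class = "gradient_scheme")
  expect_error(fit_tensor(structure(list(data = array(1, c(2, 2, 2, 7)),
                                         scheme = bad,
                                         voxel_size = c(1, 1, 1),
                                         brain_mask = label_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1))),
                                    class = "dwi_volume")),
               "rank-deficient|collinear")
})

test_that("cohort generator plants the intended group structure", {
  sim <- simulate_cohort(4, seed = 7L, grid_shape = c(32L, 32L, 8L))
  expect_equal(nrow(sim$cohort), 12L)
  expect_setequal(unique(sim$cohort$group), c("PBS-only", "FBS-hMSCs", "SS-hMSCs"))
  # all specs valid and radii non-increasing
  for (s in sim$specs) expect_true(all(diff(s$lesion_radius) <= 0))
  expect_error(simulate_cohort(4, group_effects = list(bogus = list())), "unknown group")

  # law of large numbers: planted final-timepoint mNSS ordering SS < FBS < PBS
  big <- simulate_cohort(50, seed = 21L, grid_shape = c(32L, 32L, 8L))
  sc <- score_mnss(big$mnss)
  wk5 <- sc[sc$timepoint == "wk5", ]
  m <- tapply(wk5$mnss_total, wk5$group, mean)
  expect_lt(m[["SS-hMSCs"]], m[["FBS-hMSCs"]])
  expect_lt(m[["FBS-hMSCs"]], m[["PBS-only"]])
  # and final lesion radii share the ordering
  r5 <- vapply(big$specs, function(s) s$lesion_radius[3], numeric(1))
  grp <- big$cohort$group[match(names(big$specs), big$cohort$animal)]
  mr <- tapply(r5, grp, mean)
  expect_lt(mr[["SS-hMSCs"]], mr[["FBS-hMSCs"]])
  expect_lt(mr[["FBS-hMSCs"]], mr[["PBS-only"]])

  # identical effects across groups -> equal planted means up to noise
  eff <- default_group_effects()
  eff[["FBS-hMSCs"]] <- eff[["PBS-only"]]; eff[["SS-hMSCs"]] <- eff[["PBS-only"]]
  null <- simulate_cohort(60, group_effects = eff, seed = 5L,
                          grid_shape = c(32L, 32L, 8L))
  scn <- score_mnss(null$mnss)
  wk5n <- scn[scn$timepoint == "wk5", ]
  mn <- tapply(wk5n$mnss_total, wk5n$group, mean)
  expect_lt(diff(range(mn)), 1.0)

  # same seed reproduces the cohort bit for bit
  again <- simulate_cohort(4, seed = 7L, grid_shape = c(32L, 32L, 8L))
  expect_identical(sim$cohort, again$cohort)
  expect_identical(sim$mnss, again$mnss)
})
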