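test_that("degenerate core fractions give all-rim and all-core tumors", {
  ph0 <- small_phantom(core_fraction = 0)
  tum <- ph0$tumor_mask$voxels != 0
  # no core anywhere: FLAIR minus T2 is the constant rim-level difference on
  # every tumor voxel (the shared texture cancels in the difference)
  sp <- small_phantom_spec()
  expect_equal(unique(round(ph0$flair$voxels[tum] - ph0$t2$voxels[tum], 12)),
               sp$flair_levels[2] - sp$t2_levels[2])
  m0 <- run_lesion(ph0$t2, ph0$flair, ph0$adc, ph0$tumor_mask, ph0$nawm)
  expect_identical(m0$pct_t2fm, 0)
  expect_true(is.na(m0$nadc_t2fm))

  ph1 <- small_phantom(core_fraction = 1)
  expect_equal(ph1$truth$core_fraction_raster, 1)
  m1 <- run_lesion(ph1$t2, ph1$flair, ph1$adc, ph1$tumor_mask, ph1$nawm)
  expect_identical(m1$pct_t2fm, 100)
  expect_true(is.na(m1$nadc_t2fnm))
})

test_that("rasterized core fraction matches direct lattice enumeration", {
  sp <- small_phantom_spec(core_fraction = 0.535)
  ph <- generate_lesion_phantom(sp)
  # independent brute-force count over integer voxel coordinates
  g <- expand.grid(x = 0:(sp$grid_shape[1] - 1), y = 0:(sp$grid_shape[2] - 1),
                   z = 0:(sp$grid_shape[3] - 1))
  d2 <- (g$x - sp$tumor_center_mm[1])^2 + (g$y - sp$tumor_center_mm[2])^2 +
    (g$z - sp$tumor_center_mm[3])^2
  n_tum <- sum(d2 < sp$tumor_radius_mm^2)
  r_core <- sp$tumor_radius_mm * 0.535^(1 / 3)
  n_core <- sum(d2 < r_core^2)
  expect_identical(sum(ph$tumor_mask$voxels), as.numeric(n_tum))
  expect_identical(sum(ph$truth$core_mask$voxels), as.numeric(n_core))
  expect_equal(ph$truth$core_fraction_raster, n_core / n_tum)
  expect_lt(abs(ph$truth$core_fraction_raster - 0.535), 0.02)
})

test_that("phantom generation is deterministic and geometrically consistent", {
  a <- small_phantom(noise_sd = 0.05, seed = 7L)
  b <- small_phantom(noise_sd = 0.05, seed = 7L)
  expect_identical(a$t2$voxels, b$t2$voxels)
  expect_identical(a$flair$voxels, b$flair$voxels)
  expect_identical(a$adc$voxels, b$adc$voxels)
  c2 <- small_phantom(noise_sd = 0.05, seed = 8L)
  expect_false(identical(a$t2$voxels, c2$t2$voxels))
  # core voxels are a subset of tumor voxels
  expect_true(all(a$truth$core_mask$voxels <= a$tumor_mask$voxels))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(small_phantom_spec(core_fraction = 1.2), "core_fraction")
  expect_error(phantom_spec(tumor_center_mm = c(200, 47.5, 47.5)),
               "fit inside the brain")
  expect_error(small_phantom_spec(adc_levels = c(-1, 1, 2)), "adc_levels")
  expect_error(phantom_spec(grid_shape = 32), "grid")
})

test_that("metric cohort simulator honours counts, degeneracy and the seed", {
  empty <- simulate_metric_cohort(cohort_sim_spec(n_per_group = c(0, 0, 0, 0)))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("nadc_tumor", "pct_t2fm", "os_days", "event") %in%
                    names(empty)))

  sp0 <- cohort_sim_spec(nadc_sds = rep(0, 4), seed = 3L)
  d0 <- simulate_metric_cohort(sp0)
  expect_identical(nrow(d0), 105L)
  for (g in seq_along(levels(d0$group))) {
    expect_true(all(d0$nadc_tumor[as.integer(d0$group) == g] ==
                      sp0$nadc_means[g]))
  }

  sp <- cohort_sim_spec(seed = 11L)
  d <- simulate_metric_cohort(sp)
  expect_identical(d, simulate_metric_cohort(sp, seed = 11L))
  expect_identical(as.integer(table(d$group)), c(27L, 38L, 18L, 22L))
  # law of large numbers: group means within 3 SE of the specified means
  for (g in 1:4) {
    x <- d$nadc_tumor[as.integer(d$group) == g]
    se <- sp$nadc_sds[g] / sqrt(length(x))
    expect_lt(abs(mean(x) - sp$nadc_means[g]), 3 * se)
  }
  # group membership consistent with the %T2FM cutoffs
  expect_true(all(d$pct_t2fm[d$group == "IDHm-A>=25%"] >= 25))
  expect_true(all(d$pct_t2fm[d$group == "IDHm-A<25%"] < 25))
  # institutional records are fully censored
  expect_true(all(d$event[d$cohort == "institutional"] == 0L))
  # subregion elevation strictly positive
  expect_true(all(d$nadc_t2fm > d$nadc_t2fnm))
})

test_that("phantom dataset round-trips through NIfTI bit-for-bit", {
  dir <- withr::local_tempdir()
  ph <- small_phantom(noise_sd = 0.05, seed = 5L)
  row <- write_phantom_dataset(ph, dir, "lesion001", grade = 2, age = 40)
  row2 <- write_phantom_dataset(small_phantom(core_fraction = 0.3), dir,
                                "lesion002")
  mf <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(mf), 2L)
  t2_back <- read_image_volume(file.path(dir, mf$t2_path[1]), "T2")
  expect_identical(dim(t2_back$voxels), dim(ph$t2$voxels))
  expect_identical(as.vector(t2_back$voxels), as.vector(ph$t2$voxels))
  msk <- read_image_volume(file.path(dir, mf$tumor_mask_path[1]))
  expect_identical(as.vector(msk$voxels), as.vector(ph$tumor_mask$voxels))
  truth <- jsonlite::read_json(file.path(dir, "lesion001", "truth.json"))
  expect_equal(truth$core_fraction_target, 0.5)
})
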