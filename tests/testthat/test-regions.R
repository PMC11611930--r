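make_map <- function(values, dim = c(10, 10, 10)) {
  image_volume(array(values, dim = dim), 1, modality = "subtraction")
}

test_that("subregion split partitions the tumor at threshold zero", {
  ref <- flat_volume(dim = c(10, 10, 10))
  tum_arr <- array(0, dim = c(10, 10, 10)); tum_arr[3:7, 3:7, 3:7] <- 1
  tumor <- mask_volume(tum_arr, reference = ref)

  sr0 <- split_subregions(make_map(0), tumor)
  expect_identical(sum(sr0$t2fm$voxels), 0)
  expect_identical(sr0$t2fnm$voxels, tumor$voxels)

  sr1 <- split_subregions(make_map(1), tumor)
  expect_identical(sr1$t2fm$voxels, tumor$voxels)

  set.seed(2)
  smap <- make_map(rnorm(1000))
  sr <- split_subregions(smap, tumor)
  expect_true(all(sr$t2fm$voxels + sr$t2fnm$voxels == tumor$voxels))
  expect_identical(sum(sr$t2fm$voxels * sr$t2fnm$voxels), 0)

  expect_error(split_subregions(smap, mask_volume(array(0, dim = c(10, 10, 10)),
                                                  reference = ref)), "empty")
})

test_that("noise-free phantom T2FM mask equals the true core voxel-for-voxel", {
  ph <- small_phantom(core_fraction = 0.6, noise_sd = 0)
  nawm <- rasterize_nawm_spheres(ph$nawm, ph$t2)
  smap <- build_subtraction_map(zscore_normalize(ph$t2, nawm),
                                zscore_normalize(ph$flair, nawm))
  sr <- split_subregions(smap, ph$tumor_mask)
  expect_identical(sr$t2fm$voxels, ph$truth$core_mask$voxels)
})

test_that("lesion metrics reproduce direct volumetric arithmetic", {
  ref <- flat_volume(dim = c(10, 10, 10))
  in_t2fm <- array(FALSE, dim = c(10, 10, 10)); in_t2fm[seq_len(535)] <- TRUE
  t2fm <- mask_volume(in_t2fm, reference = ref)
  t2fnm <- mask_volume(!in_t2fm, reference = ref)
  nadc <- image_volume(array(2.15, dim = c(10, 10, 10)), 1, modality = "nADC")
  m <- compute_lesion_metrics(t2fm, t2fnm, nadc)
  expect_equal(m$tumor_ml, 1.000)
  expect_equal(m$pct_t2fm, 53.5)
  expect_equal(m$t2fm_ml + m$t2fnm_ml, m$tumor_ml)
  expect_true(m$mismatch_ge25)
  # constant nADC: all three medians equal the constant
  expect_equal(c(m$nadc_tumor, m$nadc_t2fm, m$nadc_t2fnm), rep(2.15, 3))

  empty <- mask_volume(array(FALSE, dim = c(10, 10, 10)), reference = ref)
  m0 <- compute_lesion_metrics(empty, t2fnm, nadc)
  expect_identical(m0$pct_t2fm, 0)
  expect_true(is.na(m0$nadc_t2fm))
  expect_error(compute_lesion_metrics(empty, empty, nadc), "empty")
})

test_that("inclusive >=25% stratification and even-count medians", {
  ref <- flat_volume(dim = c(4, 4, 4))
  a <- array(FALSE, dim = c(4, 4, 4)); a[1:16] <- TRUE   # exactly 25%
  t2fm <- mask_volume(a, reference = ref)
  t2fnm <- mask_volume(!a, reference = ref)
  vals <- array(0, dim = c(4, 4, 4)); vals[1:16] <- c(1, 2, rep(1.5, 14))
  nadc <- image_volume(vals, 1, modality = "nADC")
  m <- compute_lesion_metrics(t2fm, t2fnm, nadc)
  expect_identical(m$pct_t2fm, 25)
  expect_true(m$mismatch_ge25)
  # median of an even-count region is the midpoint of the central pair
  two <- array(FALSE, dim = c(4, 4, 4)); two[1:2] <- TRUE
  m2 <- compute_lesion_metrics(mask_volume(two, reference = ref),
                               mask_volume(!two, reference = ref), nadc)
  expect_identical(m2$nadc_t2fm, 1.5)
})

test_that("core fraction is recovered across the whole range (64-cube grid)", {
  center <- (64 - 1) / 2
  for (cf in seq(0, 1, by = 0.2)) {
    sp <- phantom_spec(grid_shape = 64, brain_radius_mm = 30,
                       tumor_center_mm = c(center + 15, center, center),
                       tumor_radius_mm = 12.5, core_fraction = cf,
                       noise_sd = 0)
    ph <- generate_lesion_phantom(sp)
    m <- run_lesion(ph$t2, ph$flair, ph$adc, ph$tumor_mask, ph$nawm)
    expect_lt(abs(m$pct_t2fm - 100 * cf), 2)
  }
})

test_that("negating the subtraction map swaps the subregion percentages", {
  ph <- small_phantom(core_fraction = 0.5, noise_sd = 0.05, seed = 9L)
  nawm <- rasterize_nawm_spheres(ph$nawm, ph$t2)
  smap <- build_subtraction_map(zscore_normalize(ph$t2, nawm),
                                zscore_normalize(ph$flair, nawm))
  tum <- ph$tumor_mask$voxels != 0
  stopifnot(!any(smap$voxels[tum] == 0))  # a.s. with noise; guard the property
  neg <- image_volume(-smap$voxels, smap$spacing_mm, smap$affine, "subtraction")
  nadc <- build_nadc_map(ph$adc, nawm)
  m1 <- compute_lesion_metrics(split_subregions(smap, ph$tumor_mask)$t2fm,
                               split_subregions(smap, ph$tumor_mask)$t2fnm, nadc)
  m2 <- compute_lesion_metrics(split_subregions(neg, ph$tumor_mask)$t2fm,
                               split_subregions(neg, ph$tumor_mask)$t2fnm, nadc)
  expect_equal(m2$pct_t2fm, 100 - m1$pct_t2fm)
})
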