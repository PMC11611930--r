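#' Split the tumor VOI into T2FM / T2FNM subregions
#'
#' Applies the fixed threshold of 0 to the subtraction map inside the tumor
#' mask: voxels with map > 0 form the T2-FLAIR mismatch (T2FM) subregion,
#' voxels with map <= 0 the non-mismatch (T2FNM) subregion. Voxels exactly at
#' zero go to T2FNM so the two subregions always partition the tumor.
#'
#' @param sub_map subtraction `image_volume`.
#' @param tumor non-empty tumor `mask_volume` on the same grid.
#' @return list with `t2fm` and `t2fnm` `mask_volume`s.
#' @export
split_subregions <- function(sub_map, tumor) {
  assert_same_grid(sub_map, tumor, "subtraction map and tumor mask")
  tum <- tumor$voxels != 0
  if (!any(tum)) stop("tumor mask is empty")
  t2fm <- tum & (sub_map$voxels > 0)
  t2fnm <- tum & !t2fm
  list(t2fm = mask_volume(t2fm, reference = sub_map),
       t2fnm = mask_volume(t2fnm, reference = sub_map))
}

#' Per-lesion volumetric and nADC features
#'
#' Volumes in mL from voxel counts times voxel volume; percentage
#' T2FM-volume as 100 * T2FM / (T2FM + T2FNM); median nADC over the whole
#' tumor and each subregion. The median of an empty subregion is NA (not
#' zero). `mismatch_ge25` flags lesions at or above 25% T2FM-volume
#' ("mismatched").
#'
#' @param t2fm,t2fnm disjoint subregion `mask_volume`s.
#' @param nadc nADC `image_volume` on the same grid.
#' @param mismatch_threshold percent cutoff for the mismatch flag; default 25.
#' @return one-row `data.frame` (class `lesion_metrics`) with columns
#'   tumor_ml, t2fm_ml, t2fnm_ml, pct_t2fm, nadc_tumor, nadc_t2fm,
#'   nadc_t2fnm, mismatch_ge25.
#' @export
compute_lesion_metrics <- function(t2fm, t2fnm, nadc, mismatch_threshold = 25) {
  assert_same_grid(t2fm, nadc, "T2FM mask and nADC")
  assert_same_grid(t2fnm, nadc, "T2FNM mask and nADC")
  a <- t2fm$voxels != 0
  b <- t2fnm$voxels != 0
  if (any(a & b)) stop("subregion masks overlap")
  n_a <- sum(a); n_b <- sum(b)
  if (n_a + n_b == 0L) stop("both subregion masks are empty")
  vml <- voxel_ml(nadc)
  med <- function(sel) if (any(sel)) stats::median(nadc$voxels[sel]) else NA_real_
  out <- data.frame(
    tumor_ml = (n_a + n_b) * vml,
    t2fm_ml = n_a * vml,
    t2fnm_ml = n_b * vml,
    pct_t2fm = 100 * n_a / (n_a + n_b),
    nadc_tumor = med(a | b),
    nadc_t2fm = med(a),
    nadc_t2fnm = med(b)
  )
  out$mismatch_ge25 <- out$pct_t2fm >= mismatch_threshold
  class(out) <- c("lesion_metrics", class(out))
  out
}
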