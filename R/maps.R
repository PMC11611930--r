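#' NAWM reference specification
#'
#' The normal-appearing white matter (NAWM) reference is three spherical VOIs
#' in the contralateral centrum semiovale. All normalizations (z-scoring of
#' T2/FLAIR, ADC division) pool voxels over the union of the three spheres.
#'
#' @param centers_mm 3x3 matrix (one row per sphere center, world mm) or a
#'   list of three length-3 vectors.
#' @param radius_mm common sphere radius in mm; default 5.
#' @export
nawm_spec <- function(centers_mm, radius_mm = 5) {
  if (is.list(centers_mm)) centers_mm <- do.call(rbind, centers_mm)
  centers_mm <- as.matrix(centers_mm)
  if (nrow(centers_mm) != 3L || ncol(centers_mm) != 3L)
    stop("`centers_mm` must give exactly 3 sphere centers (3x3 matrix)")
  if (radius_mm <= 0) stop("`radius_mm` must be > 0")
  structure(list(centers_mm = centers_mm, radius_mm = radius_mm),
            class = "nawm_spec")
}

#' Rasterize the NAWM reference spheres
#'
#' Union of the three spheres on the reference grid (a voxel belongs to a
#' sphere iff its center lies within the radius).
#'
#' @param spec a [nawm_spec()].
#' @param reference `image_volume` providing the grid.
#' @return a `mask_volume`.
#' @export
rasterize_nawm_spheres <- function(spec, reference) {
  stopifnot(inherits(spec, "nawm_spec"), inherits(reference, "image_volume"))
  ax <- voxel_axes_mm(reference)
  rng <- rbind(range(ax$x), range(ax$y), range(ax$z))
  for (i in seq_len(3)) {
    ctr <- spec$centers_mm[i, ]
    if (any(ctr - spec$radius_mm < rng[, 1] - 0.5 * reference$spacing_mm) ||
        any(ctr + spec$radius_mm > rng[, 2] + 0.5 * reference$spacing_mm))
      stop(sprintf("NAWM sphere %d extends outside the image grid", i))
  }
  m <- rasterize_sphere(reference, spec$centers_mm[1, ], spec$radius_mm)
  for (i in 2:3)
    m <- m | rasterize_sphere(reference, spec$centers_mm[i, ], spec$radius_mm)
  if (!any(m))
    stop("NAWM rasterization is empty (radius below the voxel pitch?)")
  mask_volume(m, reference = reference)
}

#' z-score normalize a volume to the NAWM reference
#'
#' Subtracts the mean and divides by the sample SD (n-1 denominator) of the
#' voxel intensities inside the NAWM mask, so that NAWM signal is ~0 with
#' unit spread. Applied to T2 and FLAIR before subtraction.
#'
#' @param vol `image_volume`.
#' @param nawm `mask_volume` of reference voxels (non-empty, SD > 0).
#' @return normalized `image_volume` (modality suffixed with "z").
#' @export
zscore_normalize <- function(vol, nawm) {
  assert_same_grid(vol, nawm, "volume and NAWM mask")
  ref <- vol$voxels[nawm$voxels != 0]
  if (length(ref) == 0L) stop("NAWM mask is empty")
  s <- stats::sd(ref)
  if (!is.finite(s) || s <= 0)
    stop("NAWM intensity SD is zero: degenerate reference region")
  out <- (vol$voxels - mean(ref)) / s
  image_volume(out, vol$spacing_mm, vol$affine,
               modality = paste0(vol$modality, "z"))
}

#' Voxel-wise T2-FLAIR subtraction map
#'
#' Normalized T2 minus normalized FLAIR; positive values mark T2-FLAIR
#' mismatch (T2FM) tissue, non-positive values non-mismatch (T2FNM).
#'
#' @param t2z,flairz z-score normalized `image_volume`s on one grid.
#' @return `image_volume` with modality "subtraction".
#' @export
build_subtraction_map <- function(t2z, flairz) {
  assert_same_grid(t2z, flairz, "normalized T2 and FLAIR")
  image_volume(t2z$voxels - flairz$voxels, t2z$spacing_mm, t2z$affine,
               modality = "subtraction")
}

#' Normalized ADC map
#'
#' Divides the ADC map voxel-wise by the pooled mean ADC over the NAWM
#' reference voxels, making the result unit-free (NAWM mean exactly 1).
#' Because it is a pure ratio, supplying ADC in mm^2/s or 1e-3 mm^2/s gives
#' identical nADC.
#'
#' @param adc `image_volume` of ADC values.
#' @param nawm `mask_volume` of reference voxels.
#' @return `image_volume` with modality "nADC".
#' @export
build_nadc_map <- function(adc, nawm) {
  assert_same_grid(adc, nawm, "ADC and NAWM mask")
  ref <- adc$voxels[nawm$voxels != 0]
  if (length(ref) == 0L) stop("NAWM mask is empty")
  m <- mean(ref)
  if (!is.finite(m) || m <= 0)
    stop("mean NAWM ADC is not positive; check units/mask")
  image_volume(adc$voxels / m, adc$spacing_mm, adc$affine, modality = "nADC")
}
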