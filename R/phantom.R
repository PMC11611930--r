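#' Synthetic lesion phantom specification
#'
#' Defines a spherical non-enhancing lesion inside a spherical "brain" on a
#' regular grid. The tumor is T2-hyperintense throughout; an inner concentric
#' core (occupying `core_fraction` of the tumor volume, inner radius
#' r_tumor * core_fraction^(1/3)) is FLAIR-hypointense relative to the
#' hyperintense rim, reproducing the T2-FLAIR mismatch topology of a
#' "mismatched" IDH-mutant astrocytoma. ADC levels are elevated in the tumor
#' and highest in the core (microcystic-like diffusivity).
#'
#' A small deterministic sinusoidal texture (identical field in T2 and FLAIR,
#' absent from ADC) gives the NAWM reference a nonzero intensity SD even at
#' `noise_sd = 0`; because the field and therefore the NAWM SD are the same
#' in both modalities it cancels exactly in the subtraction map, so the
#' noise-free map is positive exactly on core voxels.
#'
#' @param grid_shape voxels per axis (length 3 or scalar); default 96.
#' @param spacing_mm voxel size in mm; default 1.
#' @param brain_radius_mm radius of the brain sphere; default 44.
#' @param tumor_center_mm tumor center in world mm; default 22 mm lateral of
#'   the grid center.
#' @param tumor_radius_mm tumor radius; default 15.
#' @param core_fraction target fraction of tumor volume occupied by the
#'   FLAIR-hypointense core, in [0, 1].
#' @param t2_levels,flair_levels normalized intensity means for (background
#'   brain, tumor rim, tumor core).
#' @param adc_levels ADC means (1e-3 mm^2/s) for (NAWM, tumor rim, tumor core).
#' @param noise_sd Gaussian noise SD per modality, named or ordered
#'   (t2, flair, adc); scalar recycled.
#' @param texture_amp amplitude of the deterministic brain texture.
#' @param nawm_sphere_radius_mm NAWM reference sphere radius; default 5.
#' @param subtype ground-truth group label carried into the truth record.
#' @param seed integer seed for the noise draws.
#' @export
phantom_spec <- function(grid_shape = 96, spacing_mm = 1,
                         brain_radius_mm = 44,
                         tumor_center_mm = NULL, tumor_radius_mm = 15,
                         core_fraction = 0.5,
                         t2_levels = c(1.0, 1.6, 1.8),
                         flair_levels = c(1.0, 1.8, 0.8),
                         adc_levels = c(0.8, 1.2, 2.4),
                         noise_sd = c(t2 = 0.05, flair = 0.05, adc = 0.05),
                         texture_amp = 0.02,
                         nawm_sphere_radius_mm = 5,
                         subtype = "IDHm-A", seed = 1L) {
  grid_shape <- rep(as.integer(grid_shape), length.out = 3L)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  if (any(grid_shape < 8L)) stop("grid too small")
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, 3L)
  noise_sd <- stats::setNames(as.numeric(noise_sd), c("t2", "flair", "adc"))
  center <- spacing_mm * (grid_shape - 1) / 2
  if (is.null(tumor_center_mm)) tumor_center_mm <- center + c(22, 0, 0)
  if (core_fraction < 0 || core_fraction > 1)
    stop("`core_fraction` must lie in [0, 1]")
  if (tumor_radius_mm <= 0 || brain_radius_mm <= 0 || nawm_sphere_radius_mm <= 0)
    stop("all radii must be > 0")
  if (any(adc_levels <= 0)) stop("`adc_levels` must be > 0")
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0")
  if (sqrt(sum((tumor_center_mm - center)^2)) + tumor_radius_mm > brain_radius_mm)
    stop("tumor does not fit inside the brain sphere")
  extent <- spacing_mm * (grid_shape - 1)
  if (any(center - brain_radius_mm < 0) || any(center + brain_radius_mm > extent))
    stop("brain sphere does not fit inside the voxel grid; ",
         "shrink `brain_radius_mm` or enlarge `grid_shape`")
  structure(list(
    grid_shape = grid_shape, spacing_mm = spacing_mm,
    brain_center_mm = center, brain_radius_mm = brain_radius_mm,
    tumor_center_mm = tumor_center_mm, tumor_radius_mm = tumor_radius_mm,
    core_fraction = core_fraction,
    t2_levels = t2_levels, flair_levels = flair_levels,
    adc_levels = adc_levels, noise_sd = noise_sd,
    texture_amp = texture_amp,
    nawm_sphere_radius_mm = nawm_sphere_radius_mm,
    subtype = subtype, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Generate a multi-contrast lesion phantom
#'
#' Rasterizes the brain, tumor and core spheres (voxel center strictly within
#' radius), paints modality levels, adds the deterministic texture and then
#' Gaussian noise (inside the brain only; the background stays zero as in
#' skull-stripped data). NAWM reference spheres are mirrored across the
#' mid-sagittal plane from the tumor center and spaced along the
#' anterior-posterior axis at 2.5x their radius.
#'
#' @param spec a [phantom_spec()].
#' @return list with `t2`, `flair`, `adc` (`image_volume`s), `tumor_mask`
#'   (`mask_volume`), `nawm` (a [nawm_spec()]) and `truth` (target and
#'   rasterized core fraction, tumor volume, region levels, core mask,
#'   subtype).
#' @export
generate_lesion_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ref <- image_volume(array(0, dim = spec$grid_shape), spec$spacing_mm,
                      modality = "template")
  brain <- rasterize_sphere(ref, spec$brain_center_mm, spec$brain_radius_mm)
  tumor <- rasterize_sphere(ref, spec$tumor_center_mm, spec$tumor_radius_mm)
  core_radius <- spec$tumor_radius_mm * spec$core_fraction^(1 / 3)
  if (core_radius > spec$tumor_radius_mm)
    stop("core radius exceeds tumor radius")
  core <- if (core_radius > 0)
    rasterize_sphere(ref, spec$tumor_center_mm, core_radius)
  else array(FALSE, dim = spec$grid_shape)
  core <- core & tumor
  rim <- tumor & !core

  ax <- voxel_axes_mm(ref)
  # deterministic texture, incommensurate periods so any NAWM sphere has
  # nonzero variance; identical in T2 and FLAIR, absent from ADC
  tex <- spec$texture_amp *
    (outer(outer(sin(0.83 * ax$x), cos(0.57 * ax$y), "+"),
           sin(0.31 * ax$z), "+"))

  paint <- function(levels, texture) {
    v <- array(0, dim = spec$grid_shape)
    v[brain] <- levels[1]
    v[rim] <- levels[2]
    v[core] <- levels[3]
    if (texture) v[brain] <- v[brain] + tex[brain]
    v
  }
  t2 <- paint(spec$t2_levels, TRUE)
  flair <- paint(spec$flair_levels, TRUE)
  adc <- paint(spec$adc_levels, FALSE)

  set.seed(spec$seed)
  nb <- sum(brain)
  add_noise <- function(v, sd) {
    if (sd > 0) v[brain] <- v[brain] + stats::rnorm(nb, 0, sd)
    v
  }
  t2 <- add_noise(t2, spec$noise_sd[["t2"]])
  flair <- add_noise(flair, spec$noise_sd[["flair"]])
  adc <- add_noise(adc, spec$noise_sd[["adc"]])

  # NAWM spheres mirrored contralaterally, spread along the A-P (y) axis
  mir <- spec$tumor_center_mm
  mir[1] <- 2 * spec$brain_center_mm[1] - mir[1]
  sp <- 2.5 * spec$nawm_sphere_radius_mm
  centers <- rbind(mir + c(0, -sp, 0), mir, mir + c(0, sp, 0))
  nawm <- nawm_spec(centers, spec$nawm_sphere_radius_mm)

  truth <- list(
    core_fraction_target = spec$core_fraction,
    core_fraction_raster = sum(core) / sum(tumor),
    tumor_volume_ml = sum(tumor) * prod(spec$spacing_mm) / 1000,
    subtype = spec$subtype,
    t2_levels = spec$t2_levels, flair_levels = spec$flair_levels,
    adc_levels = spec$adc_levels,
    core_mask = mask_volume(core, reference = ref)
  )
  list(
    t2 = image_volume(t2, spec$spacing_mm, modality = "T2"),
    flair = image_volume(flair, spec$spacing_mm, modality = "FLAIR"),
    adc = image_volume(adc, spec$spacing_mm, modality = "ADC"),
    tumor_mask = mask_volume(tumor, reference = ref),
    nawm = nawm,
    truth = truth
  )
}

#' Write a phantom lesion to disk as a NIfTI dataset
#'
#' Writes T2/FLAIR/ADC volumes and the tumor mask as `.nii.gz`, a JSON truth
#' sidecar, and appends one row (relative paths) to `manifest.csv` in the
#' output directory.
#'
#' @param phantom output of [generate_lesion_phantom()].
#' @param dir output directory (created if needed).
#' @param lesion_id identifier used for file names and the manifest row.
#' @param grade,age,os_days,event,cohort optional clinical fields copied into
#'   the manifest.
#' @return the manifest row as a one-row `data.frame` (invisibly).
#' @export
write_phantom_dataset <- function(phantom, dir, lesion_id,
                                  grade = NA, age = NA, os_days = NA,
                                  event = NA, cohort = "synthetic") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  rel <- function(what) file.path(lesion_id, paste0(what, ".nii.gz"))
  sub <- file.path(dir, lesion_id)
  dir.create(sub, showWarnings = FALSE)
  write_image_volume(phantom$t2, file.path(dir, rel("t2")))
  write_image_volume(phantom$flair, file.path(dir, rel("flair")))
  write_image_volume(phantom$adc, file.path(dir, rel("adc")))
  write_image_volume(phantom$tumor_mask, file.path(dir, rel("tumor_mask")))
  truth <- phantom$truth
  truth$core_mask <- NULL
  truth$nawm_centers_mm <- phantom$nawm$centers_mm
  truth$nawm_radius_mm <- phantom$nawm$radius_mm
  jsonlite::write_json(truth, file.path(sub, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  row <- data.frame(
    lesion_id = lesion_id,
    t2_path = rel("t2"), flair_path = rel("flair"), adc_path = rel("adc"),
    tumor_mask_path = rel("tumor_mask"),
    subtype = phantom$truth$subtype, grade = grade, age = age,
    os_days = os_days, event = event, cohort = cohort,
    stringsAsFactors = FALSE
  )
  mf <- file.path(dir, "manifest.csv")
  utils::write.table(row, mf, sep = ",", row.names = FALSE,
                     col.names = !file.exists(mf), append = file.exists(mf))
  invisible(row)
}
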