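# Small-geometry phantom used throughout the unit tests: 48^3 grid keeps the
# suite fast while leaving room for the brain, tumor and mirrored NAWM spheres.
small_phantom_spec <- function(core_fraction = 0.5, noise_sd = 0, seed = 1L,
                               grid = 48, ...) {
  center <- (grid - 1) / 2
  phantom_spec(grid_shape = grid, brain_radius_mm = center - 1.5,
               tumor_center_mm = c(center + 11, center, center),
               tumor_radius_mm = 9, core_fraction = core_fraction,
               nawm_sphere_radius_mm = 3.5,
               noise_sd = noise_sd, seed = seed, ...)
}

small_phantom <- function(...) generate_lesion_phantom(small_phantom_spec(...))

# flat reference volume for mask/normalization tests
flat_volume <- function(value = 0, dim = c(12, 12, 12), spacing = 1) {
  image_volume(array(value, dim = dim), spacing)
}

# jackknife-of-AUC variance of the AUC difference: independent oracle for the
# DeLong placement-value variance
jackknife_var_diff <- function(sa, sb, y) {
  n <- length(y)
  d <- vapply(seq_len(n), function(i) {
    auc_concordance(sa[-i], y[-i]) - auc_concordance(sb[-i], y[-i])
  }, numeric(1))
  (n - 1) / n * sum((d - mean(d))^2)
}
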