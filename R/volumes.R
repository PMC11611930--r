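#' Image and mask volume containers
#'
#' The pipeline works on co-registered, skull-stripped volumes that already
#' share one voxel grid; no resampling is performed anywhere. An
#' `image_volume` is a 3-D numeric array plus voxel spacing (mm), a 4x4
#' voxel-to-world affine, and a modality tag. A `mask_volume` is the same
#' with 0/1 voxels.
#'
#' @param voxels 3-D numeric array.
#' @param spacing_mm numeric length-3, voxel size per axis in mm.
#' @param affine 4x4 voxel-to-world matrix; default built from `spacing_mm`.
#' @param modality character tag, e.g. "T2", "FLAIR", "ADC", "nADC",
#'   "subtraction", "mask".
#' @return An object of class `image_volume` (or `mask_volume`, which also
#'   inherits from `image_volume`).
#' @export
image_volume <- function(voxels, spacing_mm, affine = NULL, modality = "unknown") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  if (length(voxels) == 0L) stop("empty voxel grid")
  if (!all(is.finite(voxels))) stop("voxel values must all be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be a 4x4 matrix")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm, affine = affine,
         modality = modality),
    class = "image_volume"
  )
}

#' @param reference optional `image_volume` whose spacing/affine the mask must
#'   share.
#' @rdname image_volume
#' @export
mask_volume <- function(voxels, spacing_mm, affine = NULL, reference = NULL) {
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "image_volume"))
    if (missing(spacing_mm)) spacing_mm <- reference$spacing_mm
    if (is.null(affine)) affine <- reference$affine
    if (!identical(dim(voxels), dim(reference$voxels)))
      stop("mask grid does not match reference grid")
  }
  if (is.logical(voxels)) {
    v <- array(as.numeric(voxels), dim = dim(voxels))
  } else {
    v <- voxels
  }
  if (!all(v %in% c(0, 1))) stop("mask voxels must be 0/1")
  out <- image_volume(v, spacing_mm, affine, modality = "mask")
  class(out) <- c("mask_volume", class(out))
  out
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume [%s]> %s voxels, spacing %s mm\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x")))
  invisible(x)
}

#' Check two volumes share a grid
#'
#' Same array shape and affine agreeing element-wise within `tol`. The
#' pipeline refuses to combine volumes on different grids: registration is
#' upstream and out of scope.
#'
#' @param a,b `image_volume` objects.
#' @param tol absolute tolerance on affine entries.
#' @keywords internal
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$affine - b$affine)) <= tol
}

assert_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s (shape/affine differ)", what))
  invisible(TRUE)
}

n_voxels <- function(mask) sum(mask$voxels != 0)

#' Voxel volume in mL
#' @param vol an `image_volume` or `mask_volume`.
#' @keywords internal
voxel_ml <- function(vol) prod(vol$spacing_mm) / 1000

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around RNifti; the affine is taken from / written to the
#' NIfTI sform.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality tag attached on read.
#' @export
read_image_volume <- function(path, modality = "unknown") {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  spac <- RNifti::pixdim(img)[seq_len(3)]
  aff <- structure(RNifti::xform(img), class = NULL)
  image_volume(vox, spac, aff, modality)
}

#' @param vol `image_volume` to write.
#' @param datatype NIfTI on-disk type: "double" preserves values bit-for-bit
#'   (phantom datasets); "float" (float32) suffices for derived maps.
#' @rdname read_image_volume
#' @export
write_image_volume <- function(vol, path, datatype = "double") {
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Rasterize a sphere on a volume grid
#'
#' A voxel belongs to the sphere iff its center lies strictly within the
#' radius of the sphere center (world/mm coordinates). The same rule is used
#' for tumor, core and NAWM reference spheres.
#'
#' @param reference `image_volume` providing the grid.
#' @param center_mm sphere center in world mm.
#' @param radius_mm sphere radius in mm (> 0).
#' @return logical 3-D array.
#' @keywords internal
rasterize_sphere <- function(reference, center_mm, radius_mm) {
  if (radius_mm <= 0) stop("sphere radius must be > 0")
  dm <- dim(reference$voxels)
  aff <- reference$affine
  ax <- voxel_axes_mm(reference)
  # separable squared distances along each world-aligned axis; requires the
  # affine to be axis-aligned (diagonal 3x3 block), which all pipeline grids are
  dx2 <- (ax$x - center_mm[1])^2
  dy2 <- (ax$y - center_mm[2])^2
  dz2 <- (ax$z - center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  d2 < radius_mm^2
}

# world-mm coordinates of voxel centers along each axis (0-based indices)
voxel_axes_mm <- function(vol) {
  dm <- dim(vol$voxels)
  aff <- vol$affine
  off <- aff[1:3, 4]
  sc <- diag(aff[1:3, 1:3])
  if (max(abs(aff[1:3, 1:3] - diag(sc))) > 1e-8)
    stop("non-axis-aligned affine not supported")
  list(x = off[1] + sc[1] * (seq_len(dm[1]) - 1),
       y = off[2] + sc[2] * (seq_len(dm[2]) - 1),
       z = off[3] + sc[3] * (seq_len(dm[3]) - 1))
}
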