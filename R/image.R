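#' Subject image on a template grid
#'
#' Wraps one uptake volume with its preprocessing provenance: whether the
#' image has been reference-normalized and the FWHM of any smoothing
#' already applied.
#'
#' @param subject_id character scalar.
#' @param values numeric 3-D array.
#' @param normalized logical; `TRUE` once divided by the reference-region
#'   mean.
#' @param smoothed_fwhm_mm nonnegative scalar, cumulative smoothing applied.
#' @return an object of class `subject_image`.
#' @export
subject_image <- function(subject_id, values, normalized = FALSE,
                          smoothed_fwhm_mm = 0) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    stop("`subject_id` must be a single string")
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  structure(list(subject_id = subject_id, values = values,
                 normalized = isTRUE(normalized),
                 smoothed_fwhm_mm = smoothed_fwhm_mm),
            class = "subject_image")
}

#' @export
print.subject_image <- function(x, ...) {
  cat(sprintf("subject_image '%s': %s, normalized=%s, smoothed=%g mm\n",
              x$subject_id, paste(dim(x$values), collapse = "x"),
              x$normalized, x$smoothed_fwhm_mm))
  invisible(x)
}

check_image_on_grid <- function(image, grid) {
  if (!all(dim(image$values) == grid$dims))
    stop(sprintf("image '%s' dims (%s) do not match grid (%s)",
                 image$subject_id, paste(dim(image$values), collapse = "x"),
                 paste(grid$dims, collapse = "x")))
  invisible(TRUE)
}

#' Normalize an image to its reference-region mean
#'
#' Divides every voxel by the mean uptake over the reference region (the
#' pons in the FDG-PET convention), removing per-subject global uptake
#' differences. The operation is scale-equivariant -- `normalize(c * x)`
#' equals `normalize(x)` for any `c > 0` -- and idempotent once the
#' reference mean is 1.
#'
#' @param image a [subject_image()].
#' @param grid the [template_grid()] carrying `reference_mask`.
#' @return the normalized [subject_image()] (reference mean exactly 1).
#' @export
normalize_to_reference <- function(image, grid) {
  check_image_on_grid(image, grid)
  ref_mean <- mean(image$values[grid$reference_mask])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop(sprintf("subject '%s': nonpositive reference-region mean (%g)",
                 image$subject_id, ref_mean))
  out <- image
  out$values <- image$values / ref_mean
  out$normalized <- TRUE
  out
}

#' Convert a smoothing kernel FWHM to a Gaussian sigma in voxels
#'
#' sigma = FWHM / (voxel_mm * 2 * sqrt(2 * ln 2)); the denominator constant
#' is 2.3548.
#'
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @param voxel_mm voxel edge length, mm.
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_mm) {
  fwhm_mm / (voxel_mm * 2 * sqrt(2 * log(2)))
}

# Internal: n x n one-dimensional Gaussian smoothing operator with
# half-sample symmetric reflection at the edges. Rows sum to 1 (constants
# preserved); the operator is symmetric, so columns sum to 1 and total
# image mass is conserved exactly.
gauss_operator_1d <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  radius <- max(1L, ceiling(4 * sigma))
  offsets <- (-radius):radius
  w <- exp(-offsets^2 / (2 * sigma^2))
  w <- w / sum(w)
  op <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offsets
    # reflect about the half-sample boundary until inside [1, n]
    for (rep_ in 1:8) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
      if (all(j >= 1L & j <= n)) break
    }
    for (k in seq_along(j)) op[i, j[k]] <- op[i, j[k]] + w[k]
  }
  op
}

# Internal: apply a 1-D operator along one axis of a 3-D array.
apply_along_axis <- function(arr, op, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- op %*% matrix(a, nrow = da[1])
  dim(a) <- da
  aperm(a, order(perm))
}

#' Isotropic Gaussian smoothing of a subject image
#'
#' Separable 3-D Gaussian convolution with half-sample symmetric reflection
#' at the volume edges, applied to the full volume before any masking.
#' The kernel is normalized, so constants are preserved and the total image
#' sum is conserved.
#'
#' @param image a [subject_image()].
#' @param fwhm_mm positive scalar, kernel FWHM in mm.
#' @param grid the [template_grid()] (supplies voxel size and dims).
#' @return the smoothed [subject_image()]; `smoothed_fwhm_mm` is
#'   accumulated in quadrature.
#' @export
smooth_gaussian <- function(image, fwhm_mm, grid) {
  check_image_on_grid(image, grid)
  if (!is.numeric(fwhm_mm) || fwhm_mm <= 0) stop("`fwhm_mm` must be > 0")
  sigma <- fwhm_to_sigma(fwhm_mm, grid$voxel_mm)
  out <- image
  v <- image$values
  for (ax in 1:3) {
    op <- gauss_operator_1d(grid$dims[ax], sigma)
    v <- apply_along_axis(v, op, ax)
  }
  out$values <- v
  out$smoothed_fwhm_mm <- sqrt(image$smoothed_fwhm_mm^2 + fwhm_mm^2)
  out
}

#' Flatten a subject image to its masked-voxel vector
#'
#' Extracts brain-mask voxels in the fixed lexicographic order (first axis
#' fastest). Voxels outside the mask are censored: two images that agree on
#' the mask flatten identically.
#'
#' @param image a [subject_image()].
#' @param grid the [template_grid()].
#' @return numeric vector of length `n_mask_voxels(grid)`.
#' @export
flatten <- function(image, grid) {
  check_image_on_grid(image, grid)
  v <- image$values[mask_indices(grid)]
  if (any(!is.finite(v)))
    stop(sprintf("subject '%s': non-finite values inside brain mask",
                 image$subject_id))
  v
}

#' Rebuild a subject image from a masked-voxel vector
#'
#' Inverse of [flatten()] on the mask; voxels outside the mask are 0.
#'
#' @param vec numeric vector of length `n_mask_voxels(grid)`.
#' @param grid the [template_grid()].
#' @param subject_id id for the rebuilt image.
#' @inheritParams subject_image
#' @return a [subject_image()].
#' @export
unflatten <- function(vec, grid, subject_id = "unflattened",
                      normalized = FALSE, smoothed_fwhm_mm = 0) {
  if (length(vec) != n_mask_voxels(grid))
    stop(sprintf("vector length %d != %d mask voxels",
                 length(vec), n_mask_voxels(grid)))
  arr <- array(0, dim = grid$dims)
  arr[mask_indices(grid)] <- vec
  subject_image(subject_id, arr, normalized = normalized,
                smoothed_fwhm_mm = smoothed_fwhm_mm)
}

#' Read a subject image from a NIfTI file
#'
#' @param file path to a NIfTI volume.
#' @param grid the [template_grid()] the image must live on; dims and voxel
#'   size are checked and a mismatch is a hard error.
#' @param subject_id id to assign (defaults to the file stem).
#' @return a [subject_image()].
#' @export
read_subject_image <- function(file, grid, subject_id = NULL) {
  nii <- RNifti::readNifti(file)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(file))
  if (!all(dim(nii) == grid$dims))
    stop(sprintf("image '%s' dims (%s) do not match grid (%s)", subject_id,
                 paste(dim(nii), collapse = "x"),
                 paste(grid$dims, collapse = "x")))
  pd <- RNifti::pixdim(nii)
  if (!isTRUE(all.equal(as.numeric(pd[1:3]), rep(grid$voxel_mm, 3),
                        tolerance = 1e-4)))
    stop(sprintf("image '%s' voxel size (%s) does not match grid (%g mm)",
                 subject_id, paste(signif(pd[1:3], 4), collapse = "x"),
                 grid$voxel_mm))
  subject_image(subject_id, as.array(nii))
}

#' Write a subject image as NIfTI
#'
#' @param image a [subject_image()].
#' @param grid the [template_grid()].
#' @param file output path (`.nii` or `.nii.gz`).
#' @export
write_subject_image <- function(image, grid, file) {
  check_image_on_grid(image, grid)
  write_volume(image$values, grid, file)
}
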