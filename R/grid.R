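#' Template grid: the shared voxel lattice for an analysis
#'
#' A `template_grid` bundles the voxel lattice all images of a study must
#' share: array dimensions, isotropic voxel size, a 4x4 affine, a brain
#' tissue mask and a reference-region mask (the "pons" in FDG-PET work).
#' All images entering the decomposition are censored by `brain_mask`;
#' `reference_mask` defines the region used for uptake normalization.
#'
#' Voxel order convention: masked voxels are always enumerated in
#' lexicographic order with the first array axis fastest (R's native
#' column-major order, 0-based offsets), so flattened vectors and eigenbrain
#' loadings are bit-reproducible across runs.
#'
#' @param dims integer(3), array dimensions.
#' @param voxel_mm positive scalar, isotropic voxel edge length in mm.
#' @param brain_mask logical array of dimension `dims` with at least one
#'   `TRUE` voxel.
#' @param reference_mask logical array of dimension `dims` with at least one
#'   `TRUE` voxel.
#' @param affine optional 4x4 matrix; defaults to a diagonal scaling by
#'   `voxel_mm`.
#' @return an object of class `template_grid`.
#' @export
template_grid <- function(dims, voxel_mm, brain_mask, reference_mask,
                          affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 0L))
    stop("`dims` must be 3 positive integers")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0)
    stop("`voxel_mm` must be a positive scalar")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_mm, 3), 1))
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  brain_mask <- array(as.logical(brain_mask), dim = dims)
  reference_mask <- array(as.logical(reference_mask), dim = dims)
  if (!any(brain_mask)) stop("brain mask has no voxels")
  if (!any(reference_mask)) stop("reference mask has no voxels")
  structure(
    list(dims = dims, voxel_mm = voxel_mm, affine = affine,
         brain_mask = brain_mask, reference_mask = reference_mask),
    class = "template_grid")
}

#' @export
print.template_grid <- function(x, ...) {
  cat(sprintf("template_grid: %s voxels @ %g mm, %d in brain mask, %d in reference mask\n",
              paste(x$dims, collapse = "x"), x$voxel_mm,
              sum(x$brain_mask), sum(x$reference_mask)))
  invisible(x)
}

#' Linear indices of brain-mask voxels in the fixed flattening order
#'
#' @param grid a [template_grid()].
#' @return integer vector of linear array indices (first axis fastest).
#' @export
mask_indices <- function(grid) which(grid$brain_mask)

#' Number of voxels inside the brain mask
#' @param grid a [template_grid()].
#' @export
n_mask_voxels <- function(grid) sum(grid$brain_mask)

#' Compare two grids and report any mismatch
#'
#' Used as the hard gate before any cross-image computation: images from
#' different lattices must never be combined silently.
#'
#' @param a,b [template_grid()] objects.
#' @return `TRUE` invisibly if compatible, otherwise stops with a diff
#'   report listing dims, voxel size and affine discrepancies.
#' @export
check_same_grid <- function(a, b) {
  problems <- character(0)
  if (!all(a$dims == b$dims))
    problems <- c(problems, sprintf("dims: %s vs %s",
                                    paste(a$dims, collapse = "x"),
                                    paste(b$dims, collapse = "x")))
  if (!isTRUE(all.equal(a$voxel_mm, b$voxel_mm)))
    problems <- c(problems, sprintf("voxel_mm: %g vs %g", a$voxel_mm, b$voxel_mm))
  if (!isTRUE(all.equal(a$affine, b$affine)))
    problems <- c(problems, "affine matrices differ")
  if (length(problems))
    stop("grid mismatch:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Build the default synthetic template grid
#'
#' The brain mask is the interior of the volume (a one-voxel border is
#' excluded), giving ~5000 mask voxels at the default 18x22x18 lattice.
#' The reference region stands in for the pons: a 3x3x3 block low in the
#' volume, inside the brain mask.
#'
#' @param dims integer(3) array dimensions (default `c(18, 22, 18)`).
#' @param voxel_mm voxel size in mm (default 6).
#' @return a [template_grid()].
#' @export
synthetic_grid <- function(dims = c(18L, 22L, 18L), voxel_mm = 6) {
  dims <- as.integer(dims)
  if (any(dims < 7L)) stop("synthetic grid needs dims >= 7 in every axis")
  brain <- array(FALSE, dims)
  brain[2:(dims[1] - 1L), 2:(dims[2] - 1L), 2:(dims[3] - 1L)] <- TRUE
  ref <- array(FALSE, dims)
  cx <- floor(dims[1] / 2L); cz <- 3L
  ref[cx + (0:2), 3:5, cz + (0:2)] <- TRUE
  if (!all(brain[ref])) stop("reference block fell outside the brain mask")
  template_grid(dims, voxel_mm, brain, ref)
}

#' Read a template grid from NIfTI mask files
#'
#' @param brain_mask_file,reference_mask_file paths to NIfTI volumes; voxels
#'   with value > 0.5 are taken as mask members.
#' @return a [template_grid()].
#' @export
read_grid <- function(brain_mask_file, reference_mask_file) {
  bm <- RNifti::readNifti(brain_mask_file)
  rm_ <- RNifti::readNifti(reference_mask_file)
  if (!all(dim(bm) == dim(rm_)))
    stop("brain mask and reference mask dims differ: ",
         paste(dim(bm), collapse = "x"), " vs ", paste(dim(rm_), collapse = "x"))
  pd <- RNifti::pixdim(bm)
  template_grid(dim(bm), pd[1], as.array(bm) > 0.5, as.array(rm_) > 0.5,
                affine = unclass(RNifti::xform(bm)))
}

#' Write the grid's masks as NIfTI files
#'
#' @param grid a [template_grid()].
#' @param brain_mask_file,reference_mask_file output paths.
#' @export
write_grid <- function(grid, brain_mask_file, reference_mask_file) {
  write_volume(grid$brain_mask + 0, grid, brain_mask_file)
  write_volume(grid$reference_mask + 0, grid, reference_mask_file)
  invisible(NULL)
}

# Internal: write a numeric 3-D array on `grid` as NIfTI.
write_volume <- function(values, grid, file) {
  img <- RNifti::asNifti(array(values, dim = grid$dims))
  RNifti::pixdim(img) <- rep(grid$voxel_mm, 3)
  RNifti::writeNifti(img, file)
  invisible(file)
}
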