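#' Robust per-image scaling: median-centre and interquartile-scale
#'
#' The first step of the covariance decomposition: each subject's masked,
#' reference-normalized image vector is centred on its median and divided
#' by its interquartile range, so that every subject contributes on a
#' comparable scale regardless of residual global differences. Quantiles
#' use linear interpolation between order statistics (R type 7).
#'
#' @param x numeric masked-voxel vector.
#' @param id subject id used in error messages.
#' @return the scaled vector: median 0, IQR 1.
#' @export
robust_scale <- function(x, id = "image") {
  if (any(!is.finite(x))) stop(sprintf("subject '%s': non-finite values", id))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (iqr <= .Machine$double.eps * max(1, abs(q[2])))
    stop(sprintf("subject '%s': zero interquartile range (flat image)", id))
  (x - q[2]) / iqr
}

#' Build the participant-by-voxel matrix
#'
#' Flattens each normalized image over the brain mask, robust-scales every
#' row ([robust_scale()]) and stacks them with rows sorted by subject id,
#' recording the per-subject median and IQR used.
#'
#' @param images list of normalized [subject_image()] objects.
#' @param grid the shared [template_grid()].
#' @return an object of class `image_matrix`: `values` (subject x voxel),
#'   `subject_ids`, `voxel_index` (linear array indices of the mask, fixed
#'   order), `scaling` (data.frame of medians and IQRs).
#' @export
build_matrix <- function(images, grid) {
  ids <- vapply(images, function(im) im$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(vapply(images, function(im) isTRUE(im$normalized), logical(1))))
    stop("all images must be reference-normalized before entering the matrix")
  ord <- order(ids)
  images <- images[ord]; ids <- ids[ord]
  V <- n_mask_voxels(grid)
  vals <- matrix(NA_real_, length(images), V)
  med <- iqr <- numeric(length(images))
  for (i in seq_along(images)) {
    v <- flatten(images[[i]], grid)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    med[i] <- q[2]; iqr[i] <- q[3] - q[1]
    vals[i, ] <- robust_scale(v, ids[i])
  }
  rownames(vals) <- ids
  structure(list(values = vals, subject_ids = ids,
                 voxel_index = mask_indices(grid),
                 scaling = data.frame(subject_id = ids, median = med, iqr = iqr)),
            class = "image_matrix")
}

#' @export
print.image_matrix <- function(x, ...) {
  cat(sprintf("image_matrix: %d subjects x %d masked voxels\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Singular value decomposition into eigenbrains and subject scores
#'
#' The core computation: the robust-scaled participant-by-voxel matrix is
#' submitted to a thin SVD. The right singular vectors are the
#' "eigenbrains" -- bipolar spatial patterns of relative metabolism at the
#' cohort level -- and each subject's signed scores (`U %*% diag(d)`, the
#' per-subject "eigenvalues" in the field's usage) say how strongly, and
#' in which direction, that subject expresses each pattern.
#'
#' Because pattern directionality is arbitrary, a fixed sign convention is
#' applied: each eigenbrain is flipped so its maximum-|loading| voxel is
#' positive, with the matching score column flipped in step; flips are
#' recorded in `sign_convention`.
#'
#' @param matrix an [build_matrix()] `image_matrix`.
#' @param column_center if `TRUE`, voxel-wise (column) means are removed
#'   before the SVD; the default `FALSE` performs only the per-image
#'   robust scaling.
#' @return an object of class `eb_decomposition`: `eigenbrains`
#'   (component x voxel, orthonormal rows), `singular_values`
#'   (nonincreasing), `scores` (subject x component), `pct_covariance`,
#'   `sign_convention`, `subject_ids`, `voxel_index`, `column_center`,
#'   `column_means`.
#' @export
svd_decompose <- function(matrix, column_center = FALSE) {
  stopifnot(inherits(matrix, "image_matrix"))
  X <- matrix$values
  if (any(!is.finite(X))) stop("matrix contains non-finite entries")
  cmeans <- NULL
  if (column_center) {
    cmeans <- colMeans(X)
    X <- sweep(X, 2, cmeans)
  }
  s <- svd(X)
  eb <- t(s$v)                       # component x voxel
  scores <- s$u %*% diag(s$d, length(s$d))
  flips <- integer(nrow(eb))
  for (j in seq_len(nrow(eb))) {
    jmax <- which.max(abs(eb[j, ]))
    flips[j] <- if (eb[j, jmax] < 0) -1L else 1L
    if (flips[j] < 0L) {
      eb[j, ] <- -eb[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- matrix$subject_ids
  colnames(scores) <- paste0("EB", seq_len(ncol(scores)))
  dec <- structure(
    list(eigenbrains = eb, singular_values = s$d, scores = scores,
         sign_convention = flips, subject_ids = matrix$subject_ids,
         voxel_index = matrix$voxel_index, column_center = column_center,
         column_means = cmeans),
    class = "eb_decomposition")
  dec$pct_covariance <- pct_covariance(dec)
  dec
}

#' @export
print.eb_decomposition <- function(x, ...) {
  cat(sprintf("eb_decomposition: %d subjects, %d voxels, top components explain %s%% of covariance\n",
              nrow(x$scores), ncol(x$eigenbrains),
              paste(sprintf("%.1f", utils::head(x$pct_covariance, 3)), collapse = "/")))
  invisible(x)
}

#' Percentage of covariance explained per component
#'
#' Component k explains `100 * s_k^2 / sum(s_j^2)` of the covariance across
#' images (`type = "squared"`, the default). Because "percentage of absolute
#' variance" admits a second reading, the absolute-value share
#' `100 * s_k / sum(s_j)` is also available (`type = "absolute"`).
#'
#' @param decomposition an `eb_decomposition`.
#' @param type `"squared"` (default) or `"absolute"`.
#' @return numeric vector summing to 100 over the full rank.
#' @export
pct_covariance <- function(decomposition, type = c("squared", "absolute")) {
  type <- match.arg(type)
  d <- decomposition$singular_values
  if (all(d == 0)) stop("all-zero singular value spectrum")
  w <- if (type == "squared") d^2 else d
  100 * w / sum(w)
}

#' Component retention by Horn's parallel analysis
#'
#' Compares the observed squared singular values against a permutation
#' null: in each of `n_null` replicates, every row's entries are
#' independently permuted (preserving each subject's value distribution
#' while destroying spatial covariance) and the null spectrum recorded.
#' Retention stops at the first component whose observed squared singular
#' value fails to exceed the chosen percentile of its null distribution;
#' `k_retained` is the length of that contiguous prefix.
#'
#' @param matrix an `image_matrix`.
#' @param n_null number of null replicates (>= 20), default 100.
#' @param percentile null percentile in (50, 100), default 95.
#' @param seed RNG seed for the permutations.
#' @return an object of class `horn_result`: `k_retained`,
#'   `observed_spectrum` (squared singular values),
#'   `null_percentile_spectrum`, `n_null`, `percentile`, `seed`.
#' @export
horn_parallel <- function(matrix, n_null = 100L, percentile = 95, seed = 1L) {
  stopifnot(inherits(matrix, "image_matrix"))
  if (n_null < 20L) stop("`n_null` must be >= 20")
  if (!is.numeric(percentile) || percentile <= 50 || percentile >= 100)
    stop("`percentile` must be in (50, 100)")
  X <- matrix$values
  obs <- svd(X, nu = 0, nv = 0)$d^2
  m <- min(dim(X))
  set.seed(seed)
  null_sq <- base::matrix(NA_real_, n_null, m)
  for (r in seq_len(n_null)) {
    Xp <- t(apply(X, 1, sample))
    null_sq[r, ] <- svd(Xp, nu = 0, nv = 0)$d^2
  }
  null_perc <- apply(null_sq, 2, stats::quantile, probs = percentile / 100,
                     names = FALSE, type = 7)
  exceeds <- obs > null_perc
  k <- if (!exceeds[1]) 0L else {
    fail <- which(!exceeds)
    if (length(fail)) fail[1] - 1L else m
  }
  structure(list(k_retained = as.integer(k), observed_spectrum = obs,
                 null_percentile_spectrum = null_perc,
                 n_null = as.integer(n_null), percentile = percentile,
                 seed = as.integer(seed)),
            class = "horn_result")
}

#' @export
print.horn_result <- function(x, ...) {
  cat(sprintf("horn_result: %d components retained (%d null replicates, %gth percentile)\n",
              x$k_retained, x$n_null, x$percentile))
  invisible(x)
}

#' Project a new subject image onto fitted eigenbrains
#'
#' Robust-scales the image's masked vector and takes its inner product with
#' each eigenbrain. Projecting an image used in the fit reproduces its
#' stored score row exactly (up to numerical tolerance).
#'
#' @param image a normalized [subject_image()].
#' @param decomposition an `eb_decomposition`.
#' @param grid the [template_grid()].
#' @return named numeric vector of per-component scores.
#' @export
project_image <- function(image, decomposition, grid) {
  if (!isTRUE(image$normalized))
    stop(sprintf("subject '%s': image must be reference-normalized", image$subject_id))
  if (!identical(decomposition$voxel_index, mask_indices(grid)))
    stop("decomposition voxel index does not match grid mask")
  v <- robust_scale(flatten(image, grid), image$subject_id)
  if (isTRUE(decomposition$column_center))
    v <- v - decomposition$column_means
  sc <- as.numeric(v %*% t(decomposition$eigenbrains))
  names(sc) <- colnames(decomposition$scores)
  sc
}

#' Match estimated eigenbrains to planted ground-truth patterns
#'
#' Greedy assignment maximizing |Pearson r| over masked voxels without
#' reuse of either side; reports the signed correlation and the sign flip
#' that would align each pair. A test harness for parameter-recovery
#' studies on synthetic cohorts.
#'
#' @param decomposition an `eb_decomposition`.
#' @param truth a `ground_truth` (or any k x voxel pattern matrix).
#' @return data.frame with columns `truth_pattern`, `component`, `r`,
#'   `abs_r`, `flip`, one row per planted pattern, in assignment order.
#' @export
align_components <- function(decomposition, truth) {
  P <- if (inherits(truth, "ground_truth")) truth$patterns else as.matrix(truth)
  if (is.null(P) || nrow(P) == 0L) stop("empty ground truth")
  E <- decomposition$eigenbrains
  R <- stats::cor(t(P), t(E))         # k_true x k_est
  k <- nrow(P)
  res <- data.frame(truth_pattern = integer(k), component = integer(k),
                    r = numeric(k), abs_r = numeric(k), flip = integer(k))
  A <- abs(R)
  for (step in seq_len(k)) {
    ij <- arrayInd(which.max(A), dim(A))
    i <- ij[1]; j <- ij[2]
    res[step, ] <- list(i, j, R[i, j], abs(R[i, j]), if (R[i, j] < 0) -1L else 1L)
    A[i, ] <- -Inf; A[, j] <- -Inf
  }
  res[order(res$truth_pattern), , drop = FALSE]
}

#' Run the full decomposition pipeline on a set of raw images
#'
#' Convenience wrapper chaining the preprocessing contract and the
#' decomposition: reference normalization, Gaussian smoothing, matrix
#' construction, SVD and Horn's parallel analysis.
#'
#' @param images list of raw [subject_image()] objects.
#' @param grid the [template_grid()].
#' @param fwhm_mm smoothing kernel FWHM in mm (default 6); `NULL` skips
#'   smoothing.
#' @param n_null,percentile,seed passed to [horn_parallel()].
#' @param column_center passed to [svd_decompose()].
#' @return list with elements `matrix`, `decomposition`, `horn`.
#' @export
decompose_cohort <- function(images, grid, fwhm_mm = 6, n_null = 100L,
                             percentile = 95, seed = 1L,
                             column_center = FALSE) {
  pre <- lapply(images, function(im) {
    im <- normalize_to_reference(im, grid)
    if (!is.null(fwhm_mm)) im <- smooth_gaussian(im, fwhm_mm, grid)
    im
  })
  mat <- build_matrix(pre, grid)
  dec <- svd_decompose(mat, column_center = column_center)
  horn <- horn_parallel(mat, n_null = n_null, percentile = percentile,
                        seed = seed)
  list(matrix = mat, decomposition = dec, horn = horn)
}

#' Write eigenbrain maps and scores to disk
#'
#' One NIfTI map per retained component plus a scores/percent-covariance
#' CSV.
#'
#' @param decomposition an `eb_decomposition`.
#' @param grid the [template_grid()].
#' @param dir output directory.
#' @param k how many components to write (default all subjects' worth is
#'   rarely wanted; defaults to 9 or the rank, whichever is smaller).
#' @export
write_decomposition <- function(decomposition, grid, dir,
                                k = min(9L, nrow(decomposition$eigenbrains))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_len(k))
    write_volume(unflatten(decomposition$eigenbrains[j, ], grid)$values, grid,
                 file.path(dir, sprintf("eigenbrain_%02d.nii.gz", j)))
  sc <- data.frame(subject_id = decomposition$subject_ids,
                   decomposition$scores[, seq_len(k), drop = FALSE])
  utils::write.csv(sc, file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(decomposition$pct_covariance),
                              pct_covariance = decomposition$pct_covariance),
                   file.path(dir, "pct_covariance.csv"), row.names = FALSE)
  invisible(dir)
}
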