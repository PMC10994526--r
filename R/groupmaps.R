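#' Select controls matched for sample size, age and sex
#'
#' For each sex stratum, patients are visited in subject-id order and each
#' is greedily assigned the unused control with the nearest age; ties are
#' broken by the smallest control subject id. The matched set therefore
#' has exactly the patients' size and sex composition, and the selection is
#' deterministic given the inputs.
#'
#' @param patients,controls data.frames with columns `subject_id`,
#'   `age_scan`, `sex`.
#' @param seed unused (the matching is deterministic); kept so callers can
#'   treat matching like the other seeded stages.
#' @return character vector of selected control subject ids, in patient
#'   order.
#' @export
match_controls <- function(patients, controls, seed = NULL) {
  need <- c("subject_id", "age_scan", "sex")
  if (!all(need %in% names(patients)) || !all(need %in% names(controls)))
    stop("patients and controls need columns subject_id, age_scan, sex")
  selected <- character(0)
  for (s in unique(patients$sex)) {
    pat <- patients[patients$sex == s, , drop = FALSE]
    pat <- pat[order(pat$subject_id), , drop = FALSE]
    pool <- controls[controls$sex == s, , drop = FALSE]
    if (nrow(pool) < nrow(pat))
      stop(sprintf("insufficient controls of sex %s: need %d, have %d",
                   s, nrow(pat), nrow(pool)))
    for (i in seq_len(nrow(pat))) {
      d <- abs(pool$age_scan - pat$age_scan[i])
      best <- which(d == min(d))
      if (length(best) > 1L) best <- best[order(pool$subject_id[best])[1]]
      selected[pat$subject_id[i]] <- pool$subject_id[best]
      pool <- pool[-best, , drop = FALSE]
    }
  }
  # return in the original patient order
  unname(selected[patients$subject_id])
}

#' Voxel-wise Z-score contrast map between two image groups
#'
#' Group-wise mean images are scaled by their respective voxel-level
#' standard deviation. In the default `"ratio"` mode (the literal reading
#' of that construction) the map is `m_a/s_a - m_b/s_b`; the conventional
#' control-referenced alternative `"standardized_difference"` computes
#' `(m_a - m_b)/s_b`. Voxels where either group SD is below 1e-8 are set
#' to 0 and counted as excluded (masks often include constant voxels in
#' synthetic data). SDs use the n-1 denominator.
#'
#' @param images_a,images_b lists of [subject_image()] (>= 2 each).
#' @param mode `"ratio"` (default) or `"standardized_difference"`.
#' @param grid the [template_grid()].
#' @param group_a,group_b labels recorded in the result.
#' @return an object of class `zmap`: `values` (3-D array, zero outside
#'   the brain mask), `group_a`, `group_b`, `mode`, `n_a`, `n_b`,
#'   `excluded_voxels`.
#' @export
zscore_map <- function(images_a, images_b,
                       mode = c("ratio", "standardized_difference"),
                       grid, group_a = "A", group_b = "B") {
  mode <- match.arg(mode)
  if (length(images_a) < 2L || length(images_b) < 2L)
    stop("each group needs >= 2 images")
  stack <- function(imgs) do.call(rbind, lapply(imgs, flatten, grid = grid))
  A <- stack(images_a); B <- stack(images_b)
  mstats <- function(M) {
    mu <- colMeans(M)
    sd_ <- sqrt(colSums(sweep(M, 2, mu)^2) / (nrow(M) - 1))
    list(mu = mu, sd = sd_)
  }
  a <- mstats(A); b <- mstats(B)
  bad <- a$sd < 1e-8 | b$sd < 1e-8
  z <- numeric(ncol(A))
  ok <- !bad
  if (mode == "ratio") {
    z[ok] <- a$mu[ok] / a$sd[ok] - b$mu[ok] / b$sd[ok]
  } else {
    z[ok] <- (a$mu[ok] - b$mu[ok]) / b$sd[ok]
  }
  arr <- array(0, grid$dims)
  arr[mask_indices(grid)] <- z
  structure(list(values = arr, group_a = group_a, group_b = group_b,
                 mode = mode, n_a = length(images_a), n_b = length(images_b),
                 excluded_voxels = sum(bad)),
            class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat(sprintf("zmap %s vs %s (%s): n=%d/%d, max |Z| = %.3f, %d voxels excluded\n",
              x$group_a, x$group_b, x$mode, x$n_a, x$n_b,
              max(abs(x$values)), x$excluded_voxels))
  invisible(x)
}

#' Summarize a Z-map over the brain mask
#'
#' @param zmap a [zscore_map()] result.
#' @param grid the [template_grid()].
#' @param threshold positive Z threshold (the descriptive convention in
#'   FDG-PET group comparisons is 0.3).
#' @return list: `max_abs_z`, `max_z`, `min_z`, `n_above` (Z > threshold),
#'   `n_below` (Z < -threshold), `n_beyond` (their sum), `threshold`.
#' @export
summarize_zmap <- function(zmap, grid, threshold = 0.3) {
  if (!is.numeric(threshold) || threshold <= 0) stop("`threshold` must be > 0")
  z <- zmap$values[mask_indices(grid)]
  list(max_abs_z = max(abs(z)), max_z = max(z), min_z = min(z),
       n_above = sum(z > threshold), n_below = sum(z < -threshold),
       n_beyond = sum(abs(z) > threshold), threshold = threshold)
}

#' Write a Z-map as NIfTI plus a JSON-ready summary
#'
#' @param zmap a [zscore_map()] result.
#' @param grid the [template_grid()].
#' @param file output NIfTI path.
#' @param threshold passed to [summarize_zmap()].
#' @return the summary list, invisibly.
#' @export
write_zmap <- function(zmap, grid, file, threshold = 0.3) {
  write_volume(zmap$values, grid, file)
  invisible(summarize_zmap(zmap, grid, threshold))
}
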