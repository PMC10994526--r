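#' Groups of the emulated patient cohort
#'
#' Four dementia phenotype groups -- dysexecutive Alzheimer's disease (dAD),
#' behavioural-variant frontotemporal dementia (bvFTD), behavioural
#' Alzheimer's disease (bvAD), amnestic Alzheimer's disease (aAD) -- plus
#' cognitively unimpaired controls (CU).
#' @export
cohort_groups <- function() c("dAD", "bvFTD", "bvAD", "aAD", "CU")

#' Default group means of the planted pattern loadings
#'
#' Rows dAD/bvFTD/bvAD/aAD/CU, one column per planted component. The
#' qualitative ordering mirrors the phenotype structure the analysis is
#' meant to resolve: component 1 (frontotemporal, "behavioural") loads
#' highest in bvAD; component 2 (heteromodal, "cognitive") highest in
#' dAD; component 3 (temporo-parietal) higher in dAD and aAD than bvFTD;
#' controls centre on zero.
#'
#' The columns are mutually orthogonal under cohort-size weights with
#' distinct second moments (2.0, 1.2, 0.7 between subjects), and the four
#' patient groups share a common loading-vector norm. These are deliberate
#' identifiability conditions: an SVD can only recover the individual
#' planted patterns (rather than an arbitrary rotation of their span) when
#' the subject loadings are uncorrelated across components with
#' well-separated variances, and the per-image interquartile scaling only
#' preserves that orthogonality when no group carries a systematically
#' larger signal norm (controls contribute nothing to the between-group
#' moment, so their smaller norm is a uniform scalar). Magnitudes beyond
#' that are free parameters.
#'
#' @param k_true number of planted components; columns beyond 3 are zero.
#' @export
default_loading_group_means <- function(k_true = 3) {
  base <- cbind(c(-2.575, -1.220, 2.466, -1.132, 0),
                c( 1.080, -1.815, 0.778, -2.045, 0),
                c(-0.023, -1.737, -1.055, 1.529, 0))
  m <- matrix(0, 5, k_true,
              dimnames = list(cohort_groups(), paste0("comp", seq_len(k_true))))
  kc <- min(3L, k_true)
  m[, seq_len(kc)] <- base[, seq_len(kc)]
  m
}

default_cognition_weights <- function(k_true = 3) {
  base <- rbind(stms            = c( 0.0, -0.8, -0.3),
                working_memory  = c( 0.0, -0.7, -0.2),
                verbal_fluency  = c(-0.4, -0.5,  0.0),
                visuospatial    = c( 0.0, -0.4, -0.5),
                memory          = c( 0.0, -0.3, -0.5))
  m <- matrix(0, nrow(base), k_true, dimnames = list(rownames(base), NULL))
  kc <- min(3L, k_true)
  m[, seq_len(kc)] <- base[, seq_len(kc)]
  m
}

default_behaviour_weights <- function(k_true = 3) {
  # column 1 is the intercept on the logit scale
  base <- rbind(social_disinhibition = c(-2.5, 1.8, -0.8, -0.5),
                apathy               = c(-1.2, 0.8,  0.3, -0.3),
                lack_of_empathy      = c(-3.0, 1.5, -0.5, -0.3),
                perseverative        = c(-3.0, 1.5, -0.3,  0.0),
                hyperorality         = c(-3.0, 1.4, -0.4,  0.0),
                executive_dysfunction = c(0.5, 0.5,  1.5,  0.5))
  m <- matrix(0, nrow(base), k_true + 1L,
              dimnames = list(rownames(base),
                              c("intercept", paste0("comp", seq_len(k_true)))))
  kc <- min(3L, k_true)
  m[, 1L] <- base[, 1L]
  m[, 1L + seq_len(kc)] <- base[, 1L + seq_len(kc)]
  m
}

# Per-group age-at-scan and age-at-onset normal parameters (years).
default_age_params <- function() {
  data.frame(group = c("dAD", "bvFTD", "bvAD", "aAD"),
             onset_mean = c(53.70, 54.40, 62.70, 74.90),
             onset_sd   = c(5.35, 11.20, 5.53, 4.83),
             scan_mean  = c(57.10, 59.20, 66.40, 78.60),
             scan_sd    = c(5.30, 9.97, 5.38, 4.33))
}

#' Configuration of the synthetic FDG-PET cohort generator
#'
#' Defines every parameter of the generative model: a 4-group patient
#' cohort (default sizes 52/30/7/28) plus matched controls (default 117),
#' `k_true` latent bipolar spatial metabolism patterns whose per-subject
#' loadings drive group membership, cognition (linear links, scaled-score
#' convention mean 10 / SD 3) and behavioural symptoms (logistic links),
#' a multiplicative per-subject global-uptake nuisance removed exactly by
#' reference normalization, and per-group age distributions.
#'
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @param grid_dims integer(3), default `c(18, 22, 18)`.
#' @param voxel_mm voxel size, default 6 mm.
#' @param k_true number of planted patterns (1..9), default 3.
#' @param group_sizes named integer(4) for dAD/bvFTD/bvAD/aAD, default
#'   `c(52, 30, 7, 28)`.
#' @param n_controls default 117.
#' @param loading_group_means 5 x `k_true` matrix (rows dAD, bvFTD, bvAD,
#'   aAD, CU), see [default_loading_group_means()].
#' @param loading_sd within-group SD of subject loadings, default 0.5.
#' @param noise_sd per-voxel Gaussian noise SD (relative to unit-norm
#'   patterns), default 0.05.
#' @param global_scale_range interval the per-subject multiplicative global
#'   uptake scale is drawn from, default `c(0.8, 1.2)`.
#' @param pattern_fwhm_mm smoothing applied to the white-noise fields the
#'   planted patterns are built from, default 18 mm.
#' @param baseline constant baseline uptake relative to the reference
#'   region, default 1.2.
#' @param age_params per-group onset/scan age means and SDs, see
#'   [default_age_params()].
#' @param sex_male named integer(4), males per patient group.
#' @param cognition_weights outcome x component linear link coefficients.
#' @param cognition_noise_sd latent noise SD of the cognition links.
#' @param behaviour_weights flag x (intercept + component) logistic link
#'   coefficients.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       grid_dims = c(18L, 22L, 18L),
                       voxel_mm = 6,
                       k_true = 3L,
                       group_sizes = c(dAD = 52L, bvFTD = 30L, bvAD = 7L, aAD = 28L),
                       n_controls = 117L,
                       loading_group_means = default_loading_group_means(k_true),
                       loading_sd = 0.5,
                       noise_sd = 0.05,
                       global_scale_range = c(0.8, 1.2),
                       pattern_fwhm_mm = 18,
                       baseline = 1.2,
                       age_params = default_age_params(),
                       sex_male = c(dAD = 34L, bvFTD = 13L, bvAD = 4L, aAD = 16L),
                       cognition_weights = default_cognition_weights(k_true),
                       cognition_noise_sd = 1,
                       behaviour_weights = default_behaviour_weights(k_true)) {
  group_sizes <- as.integer(group_sizes)
  names(group_sizes) <- cohort_groups()[1:4]
  if (length(group_sizes) != 4L || any(group_sizes < 1L))
    stop("`group_sizes` must be 4 positive integers")
  if (k_true < 1L || k_true > 9L) stop("`k_true` must be in 1..9")
  if (loading_sd <= 0 || noise_sd <= 0 || pattern_fwhm_mm <= 0)
    stop("all SDs and the pattern FWHM must be > 0")
  if (length(global_scale_range) != 2L || any(global_scale_range <= 0) ||
      diff(global_scale_range) < 0)
    stop("`global_scale_range` must be an interval of positive reals")
  lm_ <- as.matrix(loading_group_means)
  if (!all(dim(lm_) == c(5L, k_true)))
    stop("`loading_group_means` must be 5 x k_true")
  rownames(lm_) <- cohort_groups()
  # keep the per-group male counts consistent with rescaled group sizes
  ref_sizes <- c(dAD = 52L, bvFTD = 30L, bvAD = 7L, aAD = 28L)
  if (!all(group_sizes == ref_sizes) && all(sex_male == c(34L, 13L, 4L, 16L)))
    sex_male <- pmin(group_sizes, round(group_sizes * c(34, 13, 4, 16) / ref_sizes))
  names(sex_male) <- cohort_groups()[1:4]
  cfg <- structure(
    list(seed = as.integer(seed), grid_dims = as.integer(grid_dims),
         voxel_mm = voxel_mm, k_true = as.integer(k_true),
         group_sizes = group_sizes, n_controls = as.integer(n_controls),
         loading_group_means = lm_, loading_sd = loading_sd,
         noise_sd = noise_sd, global_scale_range = global_scale_range,
         pattern_fwhm_mm = pattern_fwhm_mm, baseline = baseline,
         age_params = age_params, sex_male = sex_male,
         cognition_weights = as.matrix(cognition_weights),
         cognition_noise_sd = cognition_noise_sd,
         behaviour_weights = as.matrix(behaviour_weights)),
    class = "sim_config")
  grid <- synthetic_grid(cfg$grid_dims, cfg$voxel_mm)
  n_subj <- sum(group_sizes) + cfg$n_controls
  if (k_true > min(n_subj, n_mask_voxels(grid)))
    stop("`k_true` exceeds the rank limit min(n_subjects, n_mask_voxels)")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed %d, grid %s @ %g mm, k_true=%d, patients %s (+%d CU)\n",
              x$seed, paste(x$grid_dims, collapse = "x"), x$voxel_mm, x$k_true,
              paste(x$group_sizes, collapse = "/"), x$n_controls))
  invisible(x)
}

# Internal: draw one smoothed, masked, mean-centred spatial field on `grid`.
smooth_field <- function(grid, fwhm_mm) {
  img <- subject_image("field", array(stats::rnorm(prod(grid$dims)), grid$dims))
  img <- smooth_gaussian(img, fwhm_mm, grid)
  v <- img$values[mask_indices(grid)]
  v - mean(v)
}

# Internal: planted patterns as a k x V orthonormal, zero-mean, bipolar
# matrix; zeroed over the reference block then Gram-Schmidt orthogonalized.
make_patterns <- function(grid, k, fwhm_mm) {
  V <- n_mask_voxels(grid)
  ref_in_mask <- grid$reference_mask[grid$brain_mask]
  P <- matrix(0, k, V)
  for (j in seq_len(k)) {
    v <- smooth_field(grid, fwhm_mm)
    # zero over the reference block, then remove the mean from the
    # remaining voxels only, so both properties hold simultaneously
    v[ref_in_mask] <- 0
    v[!ref_in_mask] <- v[!ref_in_mask] - sum(v) / sum(!ref_in_mask)
    if (j > 1L) for (i in seq_len(j - 1L)) v <- v - sum(v * P[i, ]) * P[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) stop("degenerate planted pattern; increase grid size")
    P[j, ] <- v / nv
  }
  P
}

#' Generate a complete synthetic cohort
#'
#' Produces one image per patient and control on the template grid, a
#' clinical table, and the generative ground truth. Each masked voxel is
#' `g_i * (baseline + sum_k loading_ik * pattern_k(v) + noise)` with the
#' per-subject global scale `g_i` drawn from `global_scale_range`; the
#' reference block is exactly `g_i * baseline`, so reference normalization
#' removes the global scale exactly. Deterministic given the config.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_cohort` with elements `grid`,
#'   `images` (list of [subject_image()], patients then controls),
#'   `clinical` (data.frame, one row per subject) and `truth`
#'   (`ground_truth`: planted `patterns` (k x V), `loadings` (n x k),
#'   `link_coefficients`, `seed`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- synthetic_grid(config$grid_dims, config$voxel_mm)
  V <- n_mask_voxels(grid)
  k <- config$k_true
  groups <- c(rep(cohort_groups()[1:4], times = config$group_sizes),
              rep("CU", config$n_controls))
  n <- length(groups)
  n_pat <- sum(config$group_sizes)
  ids <- c(sprintf("P%03d", seq_len(n_pat)),
           sprintf("C%03d", seq_len(config$n_controls)))

  set.seed(config$seed)
  patterns <- make_patterns(grid, k, config$pattern_fwhm_mm)
  mu <- config$loading_group_means[groups, , drop = FALSE]
  loadings <- mu + matrix(stats::rnorm(n * k, sd = config$loading_sd), n, k)
  rownames(loadings) <- ids
  # map raw uniforms onto the interval by hand so the RNG stream is
  # consumed identically whatever the interval (incl. degenerate ones)
  gscale <- config$global_scale_range[1] +
    diff(config$global_scale_range) * stats::runif(n)
  noise <- matrix(stats::rnorm(n * V, sd = config$noise_sd), n, V)

  Y <- config$baseline + loadings %*% patterns + noise
  ref_in_mask <- grid$reference_mask[grid$brain_mask]
  Y[, ref_in_mask] <- config$baseline
  Y <- Y * gscale

  midx <- mask_indices(grid)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    arr <- array(config$baseline * gscale[i], dim = grid$dims)
    arr[midx] <- Y[i, ]
    images[[i]] <- subject_image(ids[i], arr)
  }

  clinical <- simulate_clinical(config, groups, ids, loadings)

  truth <- structure(
    list(patterns = patterns, loadings = loadings,
         link_coefficients = list(cognition = config$cognition_weights,
                                  cognition_noise_sd = config$cognition_noise_sd,
                                  behaviour = config$behaviour_weights),
         global_scale = gscale, seed = config$seed),
    class = "ground_truth")
  structure(list(grid = grid, images = images, clinical = clinical,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

# Internal: clinical table given group labels and loadings. Consumes the
# cohort RNG stream after the images, in a fixed order.
simulate_clinical <- function(config, groups, ids, loadings) {
  n <- length(groups)
  ap <- config$age_params
  age_onset <- age_scan <- rep(NA_real_, n)
  pat_groups <- cohort_groups()[1:4]
  for (g in pat_groups) {
    sel <- which(groups == g)
    row <- ap[ap$group == g, ]
    age_scan[sel] <- stats::rnorm(length(sel), row$scan_mean, row$scan_sd)
    dur <- pmax(0.5, stats::rnorm(length(sel), row$scan_mean - row$onset_mean, 2))
    age_onset[sel] <- age_scan[sel] - dur
  }
  cu <- which(groups == "CU")
  if (length(cu)) {
    gmix <- sample(pat_groups, length(cu), replace = TRUE,
                   prob = config$group_sizes / sum(config$group_sizes))
    row <- ap[match(gmix, ap$group), ]
    age_scan[cu] <- stats::rnorm(length(cu), row$scan_mean, row$scan_sd)
  }

  sex <- rep(NA_character_, n)
  for (g in pat_groups) {
    sel <- which(groups == g)
    nm <- min(length(sel), config$sex_male[g])
    sex[sel] <- sample(c(rep("M", nm), rep("F", length(sel) - nm)))
  }
  if (length(cu)) {
    n_m <- round(length(cu) * sum(config$sex_male) / sum(config$group_sizes))
    sex[cu] <- sample(c(rep("M", n_m), rep("F", length(cu) - n_m)))
  }

  edu_mean <- c(dAD = 15.1, bvFTD = 15.3, bvAD = 17.0, aAD = 15.2, CU = 15.0)
  education <- round(stats::rnorm(n, edu_mean[groups], 2.5))
  education <- pmin(pmax(education, 8), 22)

  # cognition: scaled-score convention, population mean 10 / SD 3 in controls
  W <- config$cognition_weights
  latent <- loadings %*% t(W) +
    matrix(stats::rnorm(n * nrow(W), sd = config$cognition_noise_sd), n, nrow(W))
  sd0 <- sqrt(config$loading_sd^2 * rowSums(W^2) + config$cognition_noise_sd^2)
  z <- sweep(latent, 2, sd0, "/")
  stms <- as.integer(round(pmin(38, pmax(0, 34 + 3 * z[, "stms"]))))
  composites <- 10 + 3 * z[, setdiff(rownames(W), "stms"), drop = FALSE]
  colnames(composites) <- paste0("composite_", setdiff(rownames(W), "stms"))

  B <- config$behaviour_weights
  eta <- cbind(1, loadings) %*% t(B)
  flags <- matrix(stats::rbinom(length(eta), 1, stats::plogis(eta)),
                  nrow = n, dimnames = list(NULL, paste0("flag_", rownames(B))))

  # biomarkers: per-group medians with availability following the cohort's
  # collection rates; controls are amyloid-negative by design
  bm_med <- list(ptau = c(76.3, 31.1, 27.4, 80.6),
                 ati = c(0.42, 2.0, 0.41, 0.40),
                 pib_suvr = c(2.39, 1.25, 2.15, 2.60),
                 av1451_suvr = c(2.10, 1.15, 1.29, 1.73))
  avail <- list(csf = c(25 / 52, 5 / 30, 3 / 7, 3 / 28),
                amyloid = c(26 / 52, 0.01, 1 / 7, 1),
                tau = c(18 / 52, 0.01, 1 / 7, 22 / 28))
  gidx <- match(groups, pat_groups)
  draw_marker <- function(med, has) {
    m <- med[ifelse(is.na(gidx), 1L, gidx)]
    m[is.na(gidx)] <- 1
    v <- stats::rnorm(n, m, 0.15 * m)
    ifelse(has, pmax(v, 0.01), NA_real_)
  }
  has_csf <- !is.na(gidx) & stats::runif(n) < avail$csf[gidx]
  has_amy <- !is.na(gidx) & stats::runif(n) < avail$amyloid[gidx]
  has_tau <- !is.na(gidx) & stats::runif(n) < avail$tau[gidx]
  ptau <- draw_marker(bm_med$ptau, has_csf)
  ati <- draw_marker(bm_med$ati, has_csf)
  pib <- draw_marker(bm_med$pib_suvr, has_amy)
  av <- draw_marker(bm_med$av1451_suvr, has_tau)
  if (length(cu)) pib[cu] <- stats::rnorm(length(cu), 1.25, 0.08)

  apoe_avail <- c(dAD = 29 / 52, bvFTD = 28 / 30, bvAD = 1 / 7, aAD = 26 / 28, CU = 1)
  apoe_p <- c(dAD = 15 / 29, bvFTD = 6 / 28, bvAD = 0, aAD = 18 / 26, CU = 0.25)
  has_apoe <- stats::runif(n) < apoe_avail[groups]
  apoe4 <- ifelse(has_apoe, stats::rbinom(n, 1, apoe_p[groups]), NA_integer_)

  out <- data.frame(subject_id = ids, group = groups,
                    age_onset = round(age_onset, 1), age_scan = round(age_scan, 1),
                    sex = sex, education = education, stms = stms,
                    round(composites, 2), flags, apoe4 = apoe4,
                    ptau = round(ptau, 1), ati = round(ati, 2),
                    pib_suvr = round(pib, 2), av1451_suvr = round(av, 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate labelled topic maps for meta-analytic decoding
#'
#' A configurable subset of the maps are noisy copies of the planted
#' patterns with an exact Pearson correlation `signal_r` over the mask;
#' the remainder are independent smooth fields. The default of 22 maps
#' mirrors a curated topic list of coherent mental functions.
#'
#' @param config the [sim_config()] the cohort was generated from.
#' @param truth the cohort's `ground_truth`.
#' @param n_topics number of maps, default 22.
#' @param n_signal how many maps are pattern copies (default
#'   `min(k_true, n_topics)`).
#' @param signal_r Pearson correlation of signal topics with their pattern,
#'   default 0.8.
#' @return list of `topic_map` objects (`label`, `values` 3-D array);
#'   signal maps are labelled `topic_patternK`, the rest `topic_nullJ`.
#' @export
generate_topic_maps <- function(config, truth, n_topics = 22L,
                                n_signal = min(config$k_true, n_topics),
                                signal_r = 0.8) {
  stopifnot(n_topics >= 1L, n_signal <= n_topics,
            signal_r >= -1, signal_r <= 1)
  grid <- synthetic_grid(config$grid_dims, config$voxel_mm)
  set.seed(config$seed + 7919L)
  maps <- vector("list", n_topics)
  for (j in seq_len(n_topics)) {
    if (j <= n_signal) {
      p <- truth$patterns[j, ]
      q <- smooth_field(grid, config$pattern_fwhm_mm)
      q <- q - sum(q * p) / sum(p^2) * p
      q <- q / sqrt(sum(q^2))
      v <- signal_r * p + sqrt(1 - signal_r^2) * q
      label <- sprintf("topic_pattern%d", j)
    } else {
      v <- smooth_field(grid, config$pattern_fwhm_mm)
      v <- v / sqrt(sum(v^2))
      label <- sprintf("topic_null%d", j - n_signal)
    }
    arr <- array(0, grid$dims)
    arr[mask_indices(grid)] <- v
    maps[[j]] <- structure(list(label = label, values = arr),
                           class = "topic_map")
  }
  maps
}

#' Fixed categorical fixture reproducing the cohort's published table
#'
#' A deterministic 117-row clinical table whose per-group counts of the
#' five behavioural symptoms, executive dysfunction, sex, and APOE4
#' availability/carriership reproduce the published cohort description
#' cell-for-cell (e.g. social disinhibition in 25/30 bvFTD patients).
#' Continuous fields carry the per-group means; the joint distribution of
#' flags within a group is not specified by the source table and is filled
#' deterministically (flagged subjects first).
#'
#' @return a data.frame with the same schema as the synthetic clinical
#'   table (117 rows, patients only).
#' @export
make_table2_fixture <- function() {
  sizes <- c(dAD = 52L, bvFTD = 30L, bvAD = 7L, aAD = 28L)
  counts <- list(
    flag_social_disinhibition = c(0L, 25L, 5L, 1L),
    flag_apathy               = c(14L, 19L, 4L, 2L),
    flag_lack_of_empathy      = c(0L, 9L, 3L, 0L),
    flag_perseverative        = c(0L, 10L, 6L, 0L),
    flag_hyperorality         = c(1L, 15L, 3L, 0L),
    flag_executive_dysfunction = c(52L, 30L, 7L, 22L))
  males <- c(34L, 13L, 4L, 16L)
  apoe_avail <- c(29L, 28L, 1L, 26L)
  apoe_carrier <- c(15L, 6L, 0L, 18L)
  means <- data.frame(age_onset = c(53.7, 54.4, 62.7, 74.9),
                      age_scan = c(57.1, 59.2, 66.4, 78.6),
                      education = c(15.1, 15.3, 17.0, 15.2),
                      stms = c(21.2, 29.4, 30.0, 27.1))
  rows <- lapply(seq_along(sizes), function(g) {
    ng <- sizes[g]
    first_k <- function(k) c(rep(1L, k), rep(0L, ng - k))
    flags <- lapply(counts, function(cnt) first_k(cnt[g]))
    apoe <- c(rep(1L, apoe_carrier[g]),
              rep(0L, apoe_avail[g] - apoe_carrier[g]),
              rep(NA_integer_, ng - apoe_avail[g]))
    data.frame(group = names(sizes)[g],
               age_onset = means$age_onset[g], age_scan = means$age_scan[g],
               sex = c(rep("M", males[g]), rep("F", ng - males[g])),
               education = means$education[g], stms = means$stms[g],
               as.data.frame(flags), apoe4 = apoe,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("T%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to disk
#'
#' Images as NIfTI volumes, the clinical table as CSV, masks as NIfTI, and
#' the ground truth as a loadings CSV plus per-pattern NIfTI maps.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  write_grid(cohort$grid, file.path(dir, "brain_mask.nii.gz"),
             file.path(dir, "reference_mask.nii.gz"))
  for (img in cohort$images)
    write_subject_image(img, cohort$grid,
                        file.path(dir, "images", paste0(img$subject_id, ".nii.gz")))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id = rownames(cohort$truth$loadings),
                              cohort$truth$loadings),
                   file.path(dir, "true_loadings.csv"), row.names = FALSE)
  for (j in seq_len(nrow(cohort$truth$patterns)))
    write_volume(unflatten(cohort$truth$patterns[j, ], cohort$grid)$values,
                 cohort$grid, file.path(dir, sprintf("pattern_%02d.nii.gz", j)))
  invisible(dir)
}
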