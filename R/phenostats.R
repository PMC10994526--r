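#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Compares per-subject eigenbrain scores (or any continuous measure)
#' across groups. Pairwise Tukey-adjusted comparisons are computed only
#' when the omnibus test is significant at `alpha`; otherwise the pairwise
#' table is flagged as not run.
#'
#' @param scores numeric vector.
#' @param groups group labels (coerced to factor).
#' @param alpha omnibus gate for the post hoc step, default 0.05.
#' @return list: `f`, `p`, `df`, `tukey` (data.frame of pairwise
#'   differences and adjusted p, or `NULL`), `tukey_run` (logical).
#' @export
anova_tukey <- function(scores, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 subjects")
  fit <- stats::aov(scores ~ groups)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
  tukey <- NULL
  run <- is.finite(p) && p < alpha
  if (run) {
    tk <- stats::TukeyHSD(fit)$groups
    tukey <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
    names(tukey) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  }
  list(f = f, p = p, df = tab[["Df"]], tukey = tukey, tukey_run = run)
}

#' Brown-Forsythe / Levene test for variance inhomogeneity
#'
#' Tests heteroscedasticity of a measure across groups. The default
#' centres on the group medians (the Brown-Forsythe variant, robust to
#' non-normality); mean-centring gives the classical Levene test.
#'
#' @param scores numeric vector.
#' @param groups group labels.
#' @param center `"median"` (default) or `"mean"`.
#' @return list: `statistic` (F), `p`, `df`.
#' @export
brown_forsythe <- function(scores, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 subjects")
  res <- car::leveneTest(scores, groups,
                         center = if (center == "median") stats::median else mean)
  list(statistic = res[["F value"]][1], p = res[["Pr(>F)"]][1],
       df = res[["Df"]])
}

#' Multivariable linear link between eigenbrain scores and an outcome
#'
#' Ordinary least squares of the z-scored outcome on z-scored predictors,
#' so coefficients are standardized betas. Reports per-coefficient 95%
#' CIs and t-based p-values, the model R-squared / adjusted R-squared and
#' the omnibus F p-value. No multiple-testing correction is applied (one
#' model per outcome, raw p-values).
#'
#' @param scores subject x component numeric matrix.
#' @param outcome numeric vector; rows with missing outcome are dropped.
#' @param outcome_name label carried in the result.
#' @return list of class `link_result`: `outcome`, `coefficients`
#'   (data.frame: term, beta, lwr, upr, p), `r_squared`, `adj_r_squared`,
#'   `omnibus_p`, `n`, `type = "linear"`.
#' @export
linear_link <- function(scores, outcome, outcome_name = "outcome") {
  scores <- as.matrix(scores)
  keep <- stats::complete.cases(scores) & !is.na(outcome)
  X <- scores[keep, , drop = FALSE]; y <- outcome[keep]
  if (nrow(X) <= ncol(X) + 1L) stop("need n > K + 1 complete observations")
  if (stats::var(y) == 0) stop("outcome has zero variance")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient predictors")
  Z <- scale(X); yz <- as.numeric(scale(y))
  fit <- stats::lm(yz ~ Z)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  co <- sm$coefficients
  terms <- if (!is.null(colnames(X))) colnames(X) else paste0("EB", seq_len(ncol(X)))
  coefs <- data.frame(term = terms,
                      beta = co[-1, 1], lwr = ci[-1, 1], upr = ci[-1, 2],
                      p = co[-1, 4], row.names = NULL)
  fstat <- sm$fstatistic
  structure(list(outcome = outcome_name, coefficients = coefs,
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 omnibus_p = stats::pf(fstat[1], fstat[2], fstat[3],
                                       lower.tail = FALSE),
                 n = nrow(X), type = "linear", status = "ok"),
            class = "link_result")
}

#' Multivariable logistic link between eigenbrain scores and a flag
#'
#' Maximum-likelihood logistic regression of a binary outcome on z-scored
#' predictors; coefficients are reported as odds ratios per 1 SD of score
#' with Wald 95% CIs. Non-convergence and (quasi-)separation are reported
#' through the `status` field rather than as silent numbers.
#'
#' @param scores subject x component numeric matrix.
#' @param outcome logical/0-1 vector; missing rows are dropped.
#' @param outcome_name label carried in the result.
#' @return list of class `link_result`: `coefficients` (term, or, lwr,
#'   upr, p), `n`, `type = "logistic"`, `status` in
#'   `"ok" / "non_convergence" / "separation"`.
#' @export
logistic_link <- function(scores, outcome, outcome_name = "outcome") {
  scores <- as.matrix(scores)
  outcome <- as.integer(outcome)
  keep <- stats::complete.cases(scores) & !is.na(outcome)
  X <- scores[keep, , drop = FALSE]; y <- outcome[keep]
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  Z <- scale(X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ Z, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  status <- if (sep_warn || any(abs(stats::coef(fit)[-1]) > 15)) "separation"
            else if (!fit$converged) "non_convergence" else "ok"
  co <- summary(fit)$coefficients
  terms <- if (!is.null(colnames(X))) colnames(X) else paste0("EB", seq_len(ncol(X)))
  est <- co[-1, 1]; se <- co[-1, 2]
  coefs <- data.frame(term = terms, or = exp(est),
                      lwr = exp(est - 1.96 * se), upr = exp(est + 1.96 * se),
                      p = co[-1, 4], row.names = NULL)
  structure(list(outcome = outcome_name, coefficients = coefs,
                 n = length(y), type = "logistic", status = status),
            class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf("link_result (%s) for '%s', n=%d, status=%s\n",
              x$type, x$outcome, x$n, x$status))
  print(x$coefficients, digits = 3)
  if (x$type == "linear")
    cat(sprintf("R2 = %.3f, adj R2 = %.3f, omnibus p = %.3g\n",
                x$r_squared, x$adj_r_squared, x$omnibus_p))
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction (Yates), df = (r-1)(c-1). Zero row or
#' column margins are an error; small expected counts trigger a warning.
#'
#' @param contingency matrix of nonnegative integer counts, at least 2x2.
#' @return list: `statistic`, `df`, `p`, `expected`.
#' @export
chi_squared_table <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least a 2x2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(res$expected < 5))
    warning("some expected counts are below 5; the chi-squared approximation may be poor")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Cognitive composites from per-test scaled scores
#'
#' Each domain's composite is the arithmetic mean of the available scaled
#' scores of its tests. The Wisconsin Card Sorting Test and Trail Making
#' Test B are always kept as singleton domains regardless of the map.
#' Domains with no available test are missing, not zero.
#'
#' @param test_scores data.frame or matrix, subjects x tests (columns named
#'   by test).
#' @param domain_map named character vector mapping test name -> domain.
#' @return data.frame, subjects x domains.
#' @export
compute_composites <- function(test_scores, domain_map) {
  ts <- as.data.frame(test_scores)
  if (nrow(ts) == 0L || ncol(ts) == 0L) stop("empty test score table")
  norm <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  singletons <- c("wcst", "tmt_b")
  tests <- names(ts)
  if (!all(tests %in% names(domain_map)) &&
      !all(norm(tests) %in% c(norm(names(domain_map)), singletons)))
    stop("domain_map does not cover all provided tests")
  dom <- domain_map[match(norm(tests), norm(names(domain_map)))]
  dom[norm(tests) %in% singletons] <- tests[norm(tests) %in% singletons]
  out <- sapply(unique(dom), function(d) {
    cols <- which(dom == d)
    rowMeans(ts[, cols, drop = FALSE], na.rm = TRUE)
  })
  out <- as.data.frame(out)
  out[sapply(out, is.nan)] <- NA_real_
  out
}

#' Band CSF and PET biomarkers against Alzheimer's disease cut-offs
#'
#' CSF bands use the convention: p-tau < 54 pg/ml and ATI > 1.2 are not
#' consistent with Alzheimer's disease, p-tau in 54-58 and ATI in 0.8-1.2
#' are borderline, p-tau > 58 and ATI < 0.8 are consistent. PET positivity
#' uses strict inequalities: amyloid SUVR > 1.42, tau SUVR > 1.29. When
#' the two CSF bands disagree, the combined CSF call is borderline and
#' both sub-bands are reported.
#'
#' @param ptau,ati,pib_suvr,av1451_suvr numeric vectors (NA = missing);
#'   recycled to a common length.
#' @return data.frame: `ptau_band`, `ati_band`, `csf_band` (levels
#'   `not_ad`, `borderline`, `ad`), `amyloid_positive`, `tau_positive`.
#'   Rows where every marker is missing are an error.
#' @export
classify_ad_biomarkers <- function(ptau = NA, ati = NA, pib_suvr = NA,
                                   av1451_suvr = NA) {
  n <- max(length(ptau), length(ati), length(pib_suvr), length(av1451_suvr))
  ptau <- rep_len(as.numeric(ptau), n); ati <- rep_len(as.numeric(ati), n)
  pib_suvr <- rep_len(as.numeric(pib_suvr), n)
  av1451_suvr <- rep_len(as.numeric(av1451_suvr), n)
  if (any(is.na(ptau) & is.na(ati) & is.na(pib_suvr) & is.na(av1451_suvr)))
    stop("at least one biomarker must be present for every subject")
  band <- function(x, lo, hi, reverse = FALSE) {
    # reverse = TRUE: small values are AD-consistent (ATI)
    b <- ifelse(is.na(x), NA_character_,
                ifelse(x < lo, "not_ad", ifelse(x > hi, "ad", "borderline")))
    if (reverse)
      b <- ifelse(is.na(b), b, c(not_ad = "ad", borderline = "borderline",
                                 ad = "not_ad")[b])
    b
  }
  ptau_band <- band(ptau, 54, 58)
  ati_band <- band(ati, 0.8, 1.2, reverse = TRUE)
  csf_band <- ifelse(is.na(ptau_band), ati_band,
              ifelse(is.na(ati_band), ptau_band,
              ifelse(ptau_band == ati_band, ptau_band, "borderline")))
  data.frame(ptau_band = ptau_band, ati_band = ati_band, csf_band = csf_band,
             amyloid_positive = ifelse(is.na(pib_suvr), NA, pib_suvr > 1.42),
             tau_positive = ifelse(is.na(av1451_suvr), NA, av1451_suvr > 1.29),
             stringsAsFactors = FALSE)
}

#' Batch-link eigenbrain scores to a clinical table
#'
#' Runs [linear_link()] on every continuous outcome and [logistic_link()]
#' on every flag column, producing a tidy table of standardized betas /
#' odds ratios per component, one row per outcome.
#'
#' @param scores subject x component matrix, rownames = subject ids.
#' @param clinical clinical data.frame with `subject_id`.
#' @param continuous,flags column names to model; defaults cover the
#'   standard table schema.
#' @return data.frame: outcome, type, one estimate column per component,
#'   `r_squared`, `adj_r_squared`, `omnibus_p`, `n`, `status`.
#' @export
link_all_outcomes <- function(scores, clinical,
                              continuous = intersect(
                                c("age_onset", "age_scan", "education", "stms",
                                  grep("^composite_", names(clinical), value = TRUE)),
                                names(clinical)),
                              flags = grep("^flag_", names(clinical), value = TRUE)) {
  idx <- match(rownames(scores), clinical$subject_id)
  if (any(is.na(idx))) stop("scores contain subjects missing from the clinical table")
  cl <- clinical[idx, , drop = FALSE]
  one <- function(nm, type) {
    res <- tryCatch({
      if (type == "linear") linear_link(scores, cl[[nm]], nm)
      else logistic_link(scores, cl[[nm]], nm)
    }, error = function(e) NULL)
    if (is.null(res)) return(NULL)
    est <- if (type == "linear") res$coefficients$beta else res$coefficients$or
    row <- as.data.frame(as.list(stats::setNames(est, res$coefficients$term)))
    cbind(data.frame(outcome = nm, type = type), row,
          data.frame(r_squared = if (type == "linear") res$r_squared else NA,
                     adj_r_squared = if (type == "linear") res$adj_r_squared else NA,
                     omnibus_p = if (type == "linear") res$omnibus_p else NA,
                     n = res$n, status = res$status))
  }
  rows <- c(lapply(continuous, one, type = "linear"),
            lapply(flags, one, type = "logistic"))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
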