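#' Multiclass linear discriminant analysis on eigenbrain scores
#'
#' Fits the classical shared-covariance Gaussian discriminant: per-class
#' means, pooled within-class covariance (n - C denominator), priors
#' defaulting to class proportions, and discriminant axes from the
#' generalized eigenproblem of between- versus within-class scatter. With
#' C classes and full-rank features there are exactly `min(C - 1, rank)`
#' axes -- nine eigenbrain scores over four diagnostic groups yield three.
#'
#' @param scores subject x feature numeric matrix.
#' @param labels class labels (coerced to factor).
#' @param priors optional named numeric vector summing to 1; defaults to
#'   class proportions.
#' @return an object of class `lda_model`: `classes`, `means`
#'   (class x feature), `pooled_cov`, `priors`, `axes` (feature x
#'   n_axes), `grand_mean`, `variant = "standard"`.
#' @export
fit_lda <- function(scores, labels, priors = NULL) {
  X <- as.matrix(scores)
  labels <- factor(labels)
  C <- nlevels(labels); n <- nrow(X); p <- ncol(X)
  if (C < 2L) stop("need >= 2 classes")
  if (any(table(labels) < 2L)) stop("every class needs >= 2 subjects")
  if (n <= C) stop("need more subjects than classes")
  means <- t(sapply(levels(labels), function(l) colMeans(X[labels == l, , drop = FALSE])))
  if (p == 1L) means <- matrix(means, ncol = 1, dimnames = list(levels(labels), colnames(X)))
  W <- matrix(0, p, p)
  for (l in levels(labels)) {
    Xc <- sweep(X[labels == l, , drop = FALSE], 2, means[l, ])
    W <- W + crossprod(Xc)
  }
  W <- W / (n - C)
  finish_lda(X, labels, means, W, priors, variant = "standard")
}

# Internal: shared tail of the standard and robust fits.
finish_lda <- function(X, labels, means, W, priors, variant) {
  C <- nlevels(labels); p <- ncol(X)
  if (is.null(priors)) {
    priors <- as.numeric(table(labels)) / length(labels)
  } else {
    priors <- priors[levels(labels)]
    if (any(is.na(priors)) || abs(sum(priors) - 1) > 1e-8)
      stop("`priors` must be named by class and sum to 1")
  }
  names(priors) <- levels(labels)
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < max(ew$values) * 1e-10)
    stop("singular within-class scatter; reduce or decorrelate the features")
  Wih <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  grand <- colSums(means * priors)
  B <- matrix(0, p, p)
  for (l in seq_len(C)) {
    d <- means[l, ] - grand
    B <- B + priors[l] * tcrossprod(d)
  }
  M <- Wih %*% B %*% Wih
  eb <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(C - 1L, sum(eb$values > max(eb$values, 0) * 1e-8))
  axes <- Wih %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  # sign convention: largest-|weight| feature positive on each axis
  for (j in seq_len(ncol(axes))) {
    jm <- which.max(abs(axes[, j]))
    if (axes[jm, j] < 0) axes[, j] <- -axes[, j]
  }
  structure(list(classes = levels(labels), means = means, pooled_cov = W,
                 priors = priors, axes = axes, grand_mean = grand,
                 variant = variant),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model (%s): %d classes, %d features, %d discriminant axes\n",
              x$variant, length(x$classes), ncol(x$means), ncol(x$axes)))
  invisible(x)
}

#' Predict diagnoses and assemble the accuracy report
#'
#' Classifies each subject by the argmax of the shared-covariance Gaussian
#' discriminant (with the model's priors), builds the true-by-predicted
#' confusion matrix, overall and per-class accuracies, and the embedding
#' on up to three discriminant axes. The default evaluation is
#' resubstitution -- predictions on the data the model was fitted to.
#'
#' @param model an [fit_lda()] `lda_model`.
#' @param scores subject x feature matrix.
#' @param labels true class labels.
#' @return an object of class `lda_report`: `predicted`, `confusion`
#'   (true x predicted), `overall_accuracy`, `per_class_accuracy`,
#'   `embedding` (subject x <=3).
#' @export
predict_report <- function(model, scores, labels) {
  X <- as.matrix(scores)
  if (ncol(X) != ncol(model$means))
    stop(sprintf("feature count %d does not match model (%d)",
                 ncol(X), ncol(model$means)))
  labels <- factor(labels, levels = model$classes)
  Winv <- solve(model$pooled_cov)
  disc <- X %*% Winv %*% t(model$means)
  disc <- sweep(disc, 2, 0.5 * rowSums((model$means %*% Winv) * model$means), "-")
  disc <- sweep(disc, 2, log(model$priors), "+")
  pred <- factor(model$classes[max.col(disc, ties.method = "first")],
                 levels = model$classes)
  confusion <- table(true = labels, predicted = pred)
  per_class <- diag(confusion) / rowSums(confusion)
  k_emb <- min(3L, ncol(model$axes))
  emb <- sweep(X, 2, model$grand_mean) %*% model$axes[, seq_len(k_emb), drop = FALSE]
  colnames(emb) <- paste0("LD", seq_len(k_emb))
  structure(list(predicted = pred, confusion = confusion,
                 overall_accuracy = sum(diag(confusion)) / sum(confusion),
                 per_class_accuracy = per_class, embedding = emb),
            class = "lda_report")
}

#' @export
print.lda_report <- function(x, ...) {
  cat(sprintf("lda_report: overall accuracy %.1f%%\n", 100 * x$overall_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Signed logarithmic transform of scores
#'
#' `y = sign(x) * ln(1 + |x|)`: monotone, odd, fixes zero -- a
#' log-transform convention that is well-defined for the signed
#' eigenbrain scores.
#'
#' @param scores numeric vector or matrix.
#' @export
signed_log_transform <- function(scores) sign(scores) * log1p(abs(scores))

#' Robust linear discriminant analysis via high-breakdown estimates
#'
#' Replaces each class's mean and covariance with minimum covariance
#' determinant (MCD) estimates using a support fraction of
#' `floor(0.75 n)` observations per class, pools the robust scatters by
#' class size (n - C denominator weights), and proceeds exactly as
#' [fit_lda()]. Deterministic given `seed`. Classes too small for robust
#' estimation (fewer than `features + 2` members) are a loud error rather
#' than a silent fallback.
#'
#' @param scores subject x feature matrix.
#' @param labels class labels.
#' @param priors optional priors as in [fit_lda()].
#' @param seed RNG seed for the MCD subset search.
#' @return an `lda_model` with `variant = "robust"`.
#' @export
fit_robust_lda <- function(scores, labels, priors = NULL, seed = 1L) {
  X <- as.matrix(scores)
  labels <- factor(labels)
  C <- nlevels(labels); p <- ncol(X); n <- nrow(X)
  small <- names(which(table(labels) < p + 2L))
  if (length(small))
    stop("classes too small for robust (MCD) estimation with ", p,
         " features: ", paste(small, collapse = ", "),
         "; reduce the feature count or use fit_lda()")
  set.seed(seed)
  means <- matrix(NA_real_, C, p, dimnames = list(levels(labels), colnames(X)))
  W <- matrix(0, p, p)
  for (l in levels(labels)) {
    Xl <- X[labels == l, , drop = FALSE]
    rob <- MASS::cov.rob(Xl, method = "mcd",
                         quantile.used = floor(0.75 * nrow(Xl)))
    means[l, ] <- rob$center
    W <- W + (nrow(Xl) - 1) * rob$cov
  }
  W <- W / (n - C)
  finish_lda(X, labels, means, W, priors, variant = "robust")
}

#' Stratified k-fold cross-validated LDA accuracy
#'
#' An extension beyond the resubstitution report: folds are stratified by
#' class, a model is fitted on each training split and evaluated on the
#' held-out fold.
#'
#' @param scores subject x feature matrix.
#' @param labels class labels.
#' @param k number of folds, default 5.
#' @param seed RNG seed for the fold assignment.
#' @return list: `accuracy` (pooled over folds), `fold_accuracy`.
#' @export
cv_lda <- function(scores, labels, k = 5L, seed = 1L) {
  X <- as.matrix(scores); labels <- factor(labels)
  set.seed(seed)
  fold <- integer(nrow(X))
  for (l in levels(labels)) {
    idx <- which(labels == l)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  correct <- logical(nrow(X)); acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- fit_lda(X[tr, , drop = FALSE], labels[tr])
    rep_ <- predict_report(m, X[!tr, , drop = FALSE], labels[!tr])
    correct[!tr] <- rep_$predicted == labels[!tr]
    acc[f] <- rep_$overall_accuracy
  }
  list(accuracy = mean(correct), fold_accuracy = acc)
}

#' Overall accuracy implied by per-class accuracies and class sizes
#'
#' Converts per-class accuracies to integer correct counts (rounded) and
#' returns the pooled accuracy -- the arithmetic that links a confusion
#' matrix's per-class rates to its overall rate.
#'
#' @param per_class numeric vector of per-class accuracies (fractions).
#' @param class_ns integer class sizes.
#' @return overall accuracy as a fraction.
#' @export
accuracy_from_per_class <- function(per_class, class_ns) {
  if (length(per_class) != length(class_ns)) stop("length mismatch")
  sum(round(per_class * class_ns)) / sum(class_ns)
}

#' Analytic expected accuracy of a univariate shared-variance LDA
#'
#' Builds the exact decision rule of a single-feature equal-variance
#' Gaussian discriminant: priors proportional to `class_ns`, pooled
#' variance from the class SDs with n - 1 weights. The discriminant
#' functions are lines in the feature; their upper envelope partitions the
#' real line into one interval per winning class (classes can be swamped
#' and win nowhere). Expected accuracy is the prior-weighted probability
#' that each class's own normal (its printed mean and SD) falls in its
#' decision region, evaluated with normal CDFs -- no simulation involved.
#'
#' @param class_means,class_sds,class_ns per-class normal parameters and
#'   sizes (all the same length, >= 2 classes, SDs > 0).
#' @return list: `accuracy` (fraction), `boundaries` (interval endpoints),
#'   `region_class` (winning class index per interval, original order),
#'   `pooled_sd`, `priors`.
#' @export
analytic_gaussian_accuracy <- function(class_means, class_sds, class_ns) {
  k <- length(class_means)
  if (k < 2L && k != 1L) stop("need >= 1 class")
  stopifnot(length(class_sds) == k, length(class_ns) == k, all(class_sds > 0))
  if (k == 1L)
    return(list(accuracy = 1, boundaries = numeric(0), region_class = 1L,
                pooled_sd = class_sds, priors = 1))
  if (anyDuplicated(class_means))
    stop("duplicate class means give degenerate decision boundaries")
  priors <- class_ns / sum(class_ns)
  s2 <- sum((class_ns - 1) * class_sds^2) / sum(class_ns - 1)
  a <- class_means / s2
  b <- -class_means^2 / (2 * s2) + log(priors)
  ord <- order(a)
  a_o <- a[ord]; b_o <- b[ord]
  # upper envelope of the discriminant lines (convex hull trick)
  idx <- integer(0); xs <- numeric(0)
  for (m in seq_len(k)) {
    repeat {
      if (!length(idx)) break
      j <- idx[length(idx)]
      x_int <- (b_o[j] - b_o[m]) / (a_o[m] - a_o[j])
      if (length(xs) && x_int <= xs[length(xs)]) {
        idx <- idx[-length(idx)]; xs <- xs[-length(xs)]
      } else break
    }
    if (!length(idx)) idx <- m
    else {
      j <- idx[length(idx)]
      xs <- c(xs, (b_o[j] - b_o[m]) / (a_o[m] - a_o[j]))
      idx <- c(idx, m)
    }
  }
  lo <- c(-Inf, xs); hi <- c(xs, Inf)
  acc <- 0
  for (m in seq_along(idx)) {
    cls <- ord[idx[m]]
    acc <- acc + priors[cls] *
      (stats::pnorm(hi[m], class_means[cls], class_sds[cls]) -
       stats::pnorm(lo[m], class_means[cls], class_sds[cls]))
  }
  list(accuracy = acc, boundaries = xs, region_class = ord[idx],
       pooled_sd = sqrt(s2), priors = priors)
}

#' Monte-Carlo expected accuracy of the univariate shared-variance LDA
#'
#' Simulation cross-check of [analytic_gaussian_accuracy()]: draws class
#' membership from the priors and a feature value from each class's own
#' normal, classifies by the same pooled-variance discriminant rule, and
#' reports the empirical accuracy.
#'
#' @inheritParams analytic_gaussian_accuracy
#' @param n_draws number of simulated subjects, default 1e6.
#' @param seed RNG seed.
#' @return empirical accuracy (fraction).
#' @export
simulate_gaussian_accuracy <- function(class_means, class_sds, class_ns,
                                       n_draws = 1e6, seed = 1L) {
  k <- length(class_means)
  priors <- class_ns / sum(class_ns)
  s2 <- sum((class_ns - 1) * class_sds^2) / sum(class_ns - 1)
  set.seed(seed)
  g <- sample.int(k, n_draws, replace = TRUE, prob = priors)
  x <- stats::rnorm(n_draws, class_means[g], class_sds[g])
  disc <- outer(x, class_means / s2) +
    rep(-class_means^2 / (2 * s2) + log(priors), each = n_draws)
  mean(max.col(disc, ties.method = "first") == g)
}
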