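# Group-structured feature matrix used across the LDA tests.
lda_fixture <- function(seed = 1, n_per = c(20, 15, 10, 12), p = 9, sep = 3) {
  set.seed(seed)
  g <- factor(rep(paste0("g", seq_along(n_per)), times = n_per))
  centers <- matrix(stats::rnorm(length(n_per) * p, sd = sep), length(n_per), p)
  X <- centers[as.integer(g), ] + matrix(stats::rnorm(sum(n_per) * p), sum(n_per), p)
  colnames(X) <- paste0("EB", 1:p)
  list(X = X, g = g)
}

test_that("four classes with nine features yield exactly three discriminant axes", {
  fx <- lda_fixture()
  m <- fit_lda(fx$X, fx$g)
  expect_equal(ncol(m$axes), 3L)
  expect_equal(sum(m$priors), 1)
  expect_true(isSymmetric(m$pooled_cov, tol = 1e-10))
  expect_gte(min(eigen(m$pooled_cov, symmetric = TRUE)$values), 0)
})

test_that("well-separated classes are classified perfectly at resubstitution", {
  set.seed(2)
  X <- matrix(c(stats::rnorm(30, 0), stats::rnorm(30, 10)), ncol = 1)
  g <- rep(c("a", "b"), each = 30)
  m <- fit_lda(X, g)
  rep_ <- predict_report(m, X, g)
  expect_equal(rep_$overall_accuracy, 1)
  # the model classifies its own class means correctly
  mrep <- predict_report(m, m$means, rownames(m$means))
  expect_equal(as.character(mrep$predicted), rownames(m$means))
})

test_that("duplicated features make the within-class scatter singular", {
  fx <- lda_fixture()
  expect_error(fit_lda(cbind(fx$X, fx$X[, 1]), fx$g), "singular")
})

test_that("predictions agree with MASS::lda as an independent oracle", {
  fx <- lda_fixture(seed = 3, sep = 1.2)
  m <- fit_lda(fx$X, fx$g)
  rep_ <- predict_report(m, fx$X, fx$g)
  ref <- MASS::lda(fx$X, fx$g)
  ref_pred <- stats::predict(ref, fx$X)$class
  expect_equal(as.character(rep_$predicted), as.character(ref_pred))
})

test_that("the report's bookkeeping identities hold and ignore subject order", {
  fx <- lda_fixture(seed = 4, sep = 1)
  m <- fit_lda(fx$X, fx$g)
  rep_ <- predict_report(m, fx$X, fx$g)
  expect_equal(as.vector(rowSums(rep_$confusion)), as.vector(table(fx$g)))
  expect_equal(rep_$overall_accuracy,
               sum(diag(rep_$confusion)) / sum(rep_$confusion))
  perm <- sample(nrow(fx$X))
  rep_p <- predict_report(m, fx$X[perm, ], fx$g[perm])
  expect_equal(rep_p$confusion, rep_$confusion)
  expect_equal(ncol(rep_$embedding), 3L)
  expect_error(predict_report(m, fx$X[, 1:4], fx$g), "feature count")
})

test_that("resubstitution accuracy is invariant under joint invertible affine maps", {
  fx <- lda_fixture(seed = 5, sep = 1)
  m0 <- predict_report(fit_lda(fx$X, fx$g), fx$X, fx$g)$overall_accuracy
  set.seed(6)
  for (i in 1:3) {
    A <- matrix(stats::rnorm(81), 9, 9)
    while (abs(det(A)) < 1e-3) A <- matrix(stats::rnorm(81), 9, 9)
    Xt <- fx$X %*% A + matrix(stats::rnorm(9), nrow(fx$X), 9, byrow = TRUE)
    expect_equal(predict_report(fit_lda(Xt, fx$g), Xt, fx$g)$overall_accuracy, m0)
  }
})

test_that("the signed log transform is odd, fixes zero, and hits its closed forms", {
  expect_equal(signed_log_transform(0), 0)
  expect_equal(signed_log_transform(exp(1) - 1), 1)
  expect_equal(signed_log_transform(-(exp(1) - 1)), -1)
  x <- seq(-5, 5, by = 0.37)
  expect_equal(signed_log_transform(-x), -signed_log_transform(x))
  expect_true(all(diff(signed_log_transform(x)) > 0))
})

test_that("robust LDA matches standard on clean data and resists contamination", {
  # clean Gaussian classes: robust and standard agree within 2 points on
  # average over seeds
  diffs <- vapply(7:9, function(s) {
    fx <- lda_fixture(seed = s, n_per = c(30, 30, 30), p = 3, sep = 2)
    acc_std <- predict_report(fit_lda(fx$X, fx$g), fx$X, fx$g)$overall_accuracy
    acc_rob <- predict_report(fit_robust_lda(fx$X, fx$g, seed = 1),
                              fx$X, fx$g)$overall_accuracy
    abs(acc_rob - acc_std)
  }, numeric(1))
  expect_lt(mean(diffs), 0.02)
  fx <- lda_fixture(seed = 7, n_per = c(30, 30, 30), p = 3, sep = 2)
  mr <- fit_robust_lda(fx$X, fx$g, seed = 1)
  expect_identical(fit_robust_lda(fx$X, fx$g, seed = 1)$means, mr$means)

  # gross outliers in one class: evaluate on the clean subjects only
  Xc <- fx$X
  out_idx <- which(fx$g == "g1")[1:3]
  Xc[out_idx, ] <- Xc[out_idx, ] + 50
  clean <- setdiff(seq_len(nrow(Xc)), out_idx)
  acc_std_c <- mean(predict_report(fit_lda(Xc, fx$g), Xc, fx$g)$predicted[clean] ==
                    fx$g[clean])
  acc_rob_c <- mean(predict_report(fit_robust_lda(Xc, fx$g, seed = 1),
                                   Xc, fx$g)$predicted[clean] == fx$g[clean])
  expect_gte(acc_rob_c, acc_std_c)
})

test_that("robust LDA refuses classes too small for the scatter estimate", {
  fx <- lda_fixture(seed = 8, n_per = c(20, 20, 7), p = 9)
  expect_error(fit_robust_lda(fx$X, fx$g), "too small")
})

test_that("stratified cross-validation returns a sane pooled accuracy", {
  fx <- lda_fixture(seed = 9, sep = 2)
  cv <- cv_lda(fx$X, fx$g, k = 4, seed = 1)
  expect_length(cv$fold_accuracy, 4L)
  expect_gte(cv$accuracy, 0.8)
})

test_that("the analytic univariate accuracy matches closed forms and the MC oracle", {
  # symmetric two-class problem: accuracy is Phi(1)
  two <- analytic_gaussian_accuracy(c(-1, 1), c(1, 1), c(50, 50))
  expect_equal(two$accuracy, stats::pnorm(1), tolerance = 1e-12)
  expect_equal(two$boundaries, 0, tolerance = 1e-12)
  one <- analytic_gaussian_accuracy(5, 2, 10)
  expect_equal(one$accuracy, 1)
  expect_error(analytic_gaussian_accuracy(c(1, 1), c(1, 2), c(5, 5)), "duplicate")

  set.seed(10)
  for (i in 1:3) {
    k <- sample(2:5, 1)
    mu <- sort(stats::rnorm(k, sd = 5)) + seq_len(k) * 0.5
    sd_ <- stats::runif(k, 0.5, 3)
    ns <- sample(5:60, k, replace = TRUE)
    an <- analytic_gaussian_accuracy(mu, sd_, ns)$accuracy
    mc <- simulate_gaussian_accuracy(mu, sd_, ns, n_draws = 4e5, seed = i)
    expect_lt(abs(an - mc), 0.003)
  }
})

test_that("per-class accuracies and sizes pool into the overall accuracy", {
  expect_equal(accuracy_from_per_class(c(1, 0), c(10, 10)), 0.5)
  expect_equal(accuracy_from_per_class(c(0.5, 0.5), c(4, 4)), 0.5)
  expect_error(accuracy_from_per_class(c(1, 0), 10), "length")
})
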