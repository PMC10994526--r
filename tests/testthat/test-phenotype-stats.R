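test_that("ANOVA matches the closed-form F and gates the Tukey step", {
  res0 <- anova_tukey(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(res0$f, 0)
  expect_equal(res0$p, 1)
  expect_false(res0$tukey_run)

  set.seed(101)
  y <- c(stats::rnorm(20, 0), stats::rnorm(20, 10))
  g <- rep(c("a", "b"), each = 20)
  res <- anova_tukey(y, g)
  expect_lt(res$p, 1e-6)
  expect_true(res$tukey_run)
  expect_equal(nrow(res$tukey), 1L)
  # brute-force one-way F from first principles
  gm <- tapply(y, g, mean); n <- 20
  ssb <- sum(n * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  f_manual <- (ssb / 1) / (ssw / (length(y) - 2))
  expect_equal(res$f, f_manual, tolerance = 1e-10)
  expect_error(anova_tukey(1:3, c("a", "a", "b")), ">= 2")
})

test_that("the Brown-Forsythe test sees scale but not location differences", {
  set.seed(102)
  base <- stats::rnorm(30)
  y <- c(base, base + 5)          # pure location shift
  g <- rep(c("a", "b"), each = 30)
  expect_equal(brown_forsythe(y, g)$p, 1, tolerance = 1e-9)
  y2 <- c(base, 5 * stats::rnorm(30))
  expect_lt(brown_forsythe(y2, g)$p, 0.01)
  # mean-centred variant agrees with car's classical Levene
  ref <- car::leveneTest(y2, factor(g), center = mean)
  expect_equal(brown_forsythe(y2, g, center = "mean")$statistic,
               ref[["F value"]][1])
})

test_that("linear links recover exact fits and transform equivariantly", {
  set.seed(103)
  X <- matrix(stats::rnorm(60 * 3), 60, dimnames = list(NULL, paste0("EB", 1:3)))
  res <- suppressWarnings(linear_link(X, 2 * X[, 1], "toy"))  # exact fit by design
  expect_equal(res$coefficients$beta[1], 1, tolerance = 1e-8)
  expect_lt(max(abs(res$coefficients$beta[2:3])), 1e-8)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)

  y <- X[, 1] * 0.5 + stats::rnorm(60)
  a <- linear_link(X, y)
  Xf <- X; Xf[, 2] <- -Xf[, 2]
  b <- linear_link(Xf, y)
  expect_equal(b$coefficients$beta[2], -a$coefficients$beta[2])
  expect_equal(b$coefficients$beta[c(1, 3)], a$coefficients$beta[c(1, 3)])
  expect_error(linear_link(cbind(X, X[, 1]), y), "rank")
  expect_error(linear_link(X, rep(1, 60)), "variance")
})

test_that("logistic links invert under label flips and flag separation", {
  set.seed(104)
  X <- matrix(stats::rnorm(80 * 2), 80, dimnames = list(NULL, c("EB1", "EB2")))
  y <- stats::rbinom(80, 1, stats::plogis(X[, 1]))
  a <- logistic_link(X, y)
  b <- logistic_link(X, 1 - y)
  expect_equal(b$coefficients$or, 1 / a$coefficients$or, tolerance = 1e-6)
  expect_true(all(a$coefficients$lwr <= a$coefficients$or &
                  a$coefficients$or <= a$coefficients$upr))
  sep <- as.integer(X[, 1] > 0)
  expect_equal(logistic_link(X, sep)$status, "separation")
  expect_error(logistic_link(X, rep(1, 80)), "classes")
})

test_that("chi-squared tables give closed-form results and reject bad margins", {
  perfect <- chi_squared_table(matrix(c(10, 0, 0, 10), 2))
  expect_equal(perfect$statistic, 20)
  expect_equal(perfect$df, 1)
  indep <- chi_squared_table(matrix(5, 2, 2))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p, 1)
  expect_error(chi_squared_table(matrix(c(1, 0, 2, 0), 2)), "margin")
  # the fixture's social-disinhibition-by-group association is overwhelming
  fx <- make_table2_fixture()
  tab <- table(fx$group, fx$flag_social_disinhibition)
  expect_lt(suppressWarnings(chi_squared_table(tab))$p, 0.001)
})

test_that("cognitive composites average domains and keep WCST/TMT-B separate", {
  scores <- data.frame(fluency_animal = c(8, NA), fluency_letter = c(10, NA),
                       wcst = c(7, 9), tmt_b = c(5, 6), stroop = c(6, 7))
  map <- c(fluency_animal = "verbal_fluency", fluency_letter = "verbal_fluency",
           wcst = "flexibility", tmt_b = "flexibility", stroop = "inhibition")
  comp <- compute_composites(scores, map)
  expect_equal(comp$verbal_fluency, c(9, NA_real_))
  expect_equal(comp$wcst, c(7, 9))       # singleton despite the map
  expect_equal(comp$tmt_b, c(5, 6))
  expect_equal(comp$inhibition, c(6, 7))
  expect_error(compute_composites(scores[0, 0], map), "empty")
})

test_that("biomarker banding honours the published cut-offs", {
  # dAD-typical CSF values are consistent with Alzheimer pathology
  r <- classify_ad_biomarkers(ptau = 76.3, ati = 0.42)
  expect_equal(r$ptau_band, "ad")
  expect_equal(r$ati_band, "ad")
  expect_equal(r$csf_band, "ad")
  # PET positivity is strict: exactly 1.29 is tau-negative, 2.39 amyloid-positive
  r2 <- classify_ad_biomarkers(pib_suvr = 2.39, av1451_suvr = 1.29)
  expect_true(r2$amyloid_positive)
  expect_false(r2$tau_positive)
  # disagreeing CSF bands collapse to borderline, sub-bands preserved
  r3 <- classify_ad_biomarkers(ptau = 30, ati = 0.5)
  expect_equal(r3$ptau_band, "not_ad")
  expect_equal(r3$ati_band, "ad")
  expect_equal(r3$csf_band, "borderline")
  expect_equal(classify_ad_biomarkers(ptau = 56)$ptau_band, "borderline")
  expect_error(classify_ad_biomarkers(), "at least one")
})

test_that("batch linking produces one row per outcome with component estimates", {
  coh <- tiny_cohort(seed = 1)
  n <- nrow(coh$truth$loadings)
  scores <- coh$truth$loadings + matrix(stats::rnorm(n * 3, sd = 0.1), n)
  colnames(scores) <- paste0("EB", 1:3)
  tab <- link_all_outcomes(scores, coh$clinical)
  expect_true(all(c("outcome", "EB1", "EB2", "EB3", "status") %in% names(tab)))
  expect_true(any(tab$type == "linear") && any(tab$type == "logistic"))
  expect_true(all(tab$n <= n))
})
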