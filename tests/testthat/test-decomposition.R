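test_that("robust scaling centres on the median and scales by the IQR", {
  expect_equal(robust_scale(c(1, 2, 3, 4, 5)), c(-1, -0.5, 0, 0.5, 1))
  expect_error(robust_scale(rep(2, 10), id = "flat_subj"), "flat_subj")
  set.seed(21)
  for (i in 1:5) {
    x <- robust_scale(stats::rnorm(101, mean = 7, sd = 3))
    expect_lt(abs(stats::median(x)), 1e-9)
    expect_lt(abs(diff(stats::quantile(x, c(0.25, 0.75), type = 7)) - 1), 1e-9)
  }
})

test_that("the participant-by-voxel matrix has scaled rows in subject-id order", {
  grid <- test_grid()
  imgs <- lapply(c("s2", "s3", "s1"), function(id)
    normalize_to_reference(random_image(grid, seed = match(id, c("s1", "s2", "s3")),
                                        id = id), grid))
  mat <- build_matrix(imgs, grid)
  expect_equal(dim(mat$values), c(3L, n_mask_voxels(grid)))
  expect_identical(mat$subject_ids, c("s1", "s2", "s3"))
  for (i in 1:3) {
    expect_lt(abs(stats::median(mat$values[i, ])), 1e-9)
    expect_lt(abs(diff(stats::quantile(mat$values[i, ], c(.25, .75), type = 7)) - 1), 1e-9)
  }
  # input order is immaterial: the labelled matrix is identical
  mat2 <- build_matrix(imgs[c(3, 1, 2)], grid)
  expect_identical(mat2$values, mat$values)
  expect_error(build_matrix(imgs[c(1, 1)], grid), "duplicate")
  raw <- random_image(grid, seed = 9, id = "raw")
  expect_error(build_matrix(c(imgs, list(raw)), grid), "normalized")
})

test_that("the SVD returns the exact spectrum on a diagonal matrix", {
  mat <- structure(list(values = matrix(c(2, 0, 0, 1), 2, 2, byrow = TRUE),
                        subject_ids = c("a", "b"), voxel_index = 1:2,
                        scaling = NULL), class = "image_matrix")
  dec <- svd_decompose(mat)
  expect_equal(dec$singular_values, c(2, 1))
  expect_equal(pct_covariance(dec), c(80, 20))
  expect_equal(pct_covariance(dec, type = "absolute"), c(200 / 3, 100 / 3))
})

test_that("equal singular values split covariance evenly and shares sum to 100", {
  mat <- structure(list(values = diag(2), subject_ids = c("a", "b"),
                        voxel_index = 1:2, scaling = NULL),
                   class = "image_matrix")
  expect_equal(pct_covariance(svd_decompose(mat)), c(50, 50))
  coh <- tiny_cohort(seed = 1)
  res <- decompose_cohort(coh$images[1:20], coh$grid, fwhm_mm = 6, n_null = 20)
  expect_equal(sum(res$decomposition$pct_covariance), 100, tolerance = 1e-6)
})

test_that("the decomposition reconstructs the matrix and obeys its invariants", {
  coh <- tiny_cohort(seed = 1)
  res <- decompose_cohort(coh$images[1:25], coh$grid, fwhm_mm = 6, n_null = 20)
  dec <- res$decomposition
  X <- res$matrix$values
  expect_lt(max(abs(dec$scores %*% dec$eigenbrains - X)), 1e-8)
  EBt <- dec$eigenbrains %*% t(dec$eigenbrains)
  expect_lt(max(abs(EBt - diag(nrow(EBt)))), 1e-8)
  # scores = scaled matrix times eigenbrain transpose
  expect_lt(max(abs(X %*% t(dec$eigenbrains) - dec$scores)), 1e-8)
  # sign convention: the maximum-|loading| voxel of each eigenbrain is positive
  for (j in seq_len(nrow(dec$eigenbrains)))
    expect_gt(dec$eigenbrains[j, which.max(abs(dec$eigenbrains[j, ]))], 0)
  # flipping an eigenbrain and its score column together leaves the fit intact
  flipped_recon <- (-dec$scores[, 1]) %*% t(-dec$eigenbrains[1, ]) +
    dec$scores[, -1] %*% dec$eigenbrains[-1, ]
  expect_lt(max(abs(flipped_recon - X)), 1e-8)
})

test_that("score columns are orthogonal; sample correlation vanishes under column centering", {
  coh <- tiny_cohort(seed = 1)
  pre <- lapply(coh$images[1:30], function(im)
    normalize_to_reference(im, coh$grid))
  mat <- build_matrix(pre, coh$grid)
  dec <- svd_decompose(mat)
  S <- dec$scores
  ip <- crossprod(S)
  expect_lt(max(abs(ip - diag(diag(ip)))) / max(diag(ip)), 1e-8)
  decc <- svd_decompose(mat, column_center = TRUE)
  cc <- stats::cor(decc$scores[, 1:5])
  expect_lt(max(abs(cc - diag(5))), 1e-8)
})

test_that("projection reproduces training scores and isolates planted patterns", {
  coh <- tiny_cohort(seed = 1)
  grid <- coh$grid
  pre <- lapply(coh$images[1:20], function(im) normalize_to_reference(im, grid))
  mat <- build_matrix(pre, grid)
  dec <- svd_decompose(mat)
  img <- pre[[7]]
  sc <- project_image(img, dec, grid)
  expect_lt(max(abs(sc - dec$scores[img$subject_id, ])), 1e-8)

  # under the full study conditions an image that is baseline plus one
  # planted pattern scores dominantly on the matched component
  full <- full_pipeline()
  fgrid <- full$cohort$grid
  fcfg <- full$cohort$config
  fdec <- full$pipeline$decomposition
  probe <- unflatten(fcfg$baseline + 5 * full$cohort$truth$patterns[2, ],
                     fgrid, "probe", normalized = TRUE)
  probe$values[!fgrid$brain_mask] <- fcfg$baseline
  al <- align_components(fdec, full$cohort$truth)
  psc <- project_image(probe, fdec, fgrid)
  expect_equal(unname(which.max(abs(psc))),
               al$component[al$truth_pattern == 2])

  # a signal-free image scores near zero relative to the cohort score spread
  set.seed(77)
  null_img <- unflatten(fcfg$baseline + stats::rnorm(n_mask_voxels(fgrid),
                                                     sd = fcfg$noise_sd),
                        fgrid, "null", normalized = TRUE)
  nsc <- project_image(null_img, fdec, fgrid)
  spread <- apply(fdec$scores[, 1:3], 2, stats::sd)
  expect_true(all(abs(nsc[1:3]) < 0.5 * spread))
})

test_that("scores are invariant to a global multiplicative factor on the raw image", {
  coh <- tiny_cohort(seed = 1)
  grid <- coh$grid
  pre <- lapply(coh$images[1:15], function(im) normalize_to_reference(im, grid))
  dec <- svd_decompose(build_matrix(pre, grid))
  raw <- coh$images[[3]]
  scaled <- raw; scaled$values <- raw$values * 4.2
  a <- project_image(normalize_to_reference(raw, grid), dec, grid)
  b <- project_image(normalize_to_reference(scaled, grid), dec, grid)
  expect_lt(max(abs(a - b)), 1e-8)
})

test_that("component alignment finds identities, records flips, and stays low on noise", {
  coh <- tiny_cohort(seed = 1)
  P <- coh$truth$patterns
  fake <- structure(list(eigenbrains = P, scores = NULL), class = "eb_decomposition")
  al <- align_components(fake, coh$truth)
  expect_equal(al$r, rep(1, 3), tolerance = 1e-12)
  fake$eigenbrains <- -P
  al2 <- align_components(fake, coh$truth)
  expect_equal(al2$r, rep(-1, 3), tolerance = 1e-12)
  expect_true(all(al2$flip == -1L))
  set.seed(5)
  rand <- matrix(stats::rnorm(3 * ncol(P)), 3)
  al3 <- align_components(structure(list(eigenbrains = rand),
                                    class = "eb_decomposition"), coh$truth)
  expect_lt(mean(al3$abs_r), 0.2)
  expect_error(align_components(fake, structure(list(patterns = NULL),
                                                class = "ground_truth")),
               "empty")
})

test_that("Horn retention is empty on white noise and monotone in the percentile", {
  set.seed(31)
  k0 <- integer(50)
  for (s in 1:50) {
    X <- matrix(stats::rnorm(20 * 500), 20, 500)
    mat <- structure(list(values = X, subject_ids = as.character(1:20),
                          voxel_index = 1:500, scaling = NULL),
                     class = "image_matrix")
    k0[s] <- horn_parallel(mat, n_null = 100, percentile = 95, seed = s)$k_retained
  }
  expect_gte(mean(k0 == 0L), 0.8)

  coh <- tiny_cohort(seed = 1)
  res <- decompose_cohort(coh$images, coh$grid, fwhm_mm = 6, n_null = 25, seed = 2)
  k95 <- res$horn$k_retained
  k99 <- horn_parallel(res$matrix, n_null = 25, percentile = 99, seed = 2)$k_retained
  expect_lte(k99, k95)
  expect_error(horn_parallel(res$matrix, n_null = 25, percentile = 40), "percentile")
  expect_error(horn_parallel(res$matrix, n_null = 5), "n_null")
})
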