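# PCA, Fisher LDA, cross-validation, score export.

test_that("rank-1 data puts 100% of variance on PC1", {
  set.seed(1)
  v <- c(1, 2, 3)
  x <- outer(rnorm(10), v) + matrix(5, 10, 3)
  m <- pca_fit(x)
  expect_equal(100 * m$variance[1] / m$total_variance, 100, tolerance = 1e-8)
})

test_that("PCA matches the covariance eigendecomposition on a toy set", {
  x <- matrix(c(0, 0, 1, 2, 3, 3, 2, 0, 4, 4, 1, 3), ncol = 2)
  m <- pca_fit(x)
  ev <- eigen(cov(x), symmetric = TRUE)  # independent oracle
  expect_equal(m$variance, ev$values, tolerance = 1e-10)
  for (j in 1:2) {
    cosang <- abs(sum(m$loadings[, j] * ev$vectors[, j]))
    expect_equal(cosang, 1, tolerance = 1e-10)
  }
  expect_equal(sum(m$all_variances), m$total_variance, tolerance = 1e-8)
})

test_that("keeping all components reconstructs the data exactly", {
  set.seed(2)
  x <- matrix(rnorm(60), 12, 5)
  m <- pca_fit(x)
  back <- pca_inverse(m, pca_transform(m, x))
  expect_equal(back, x, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("loading sign convention: largest-magnitude element is positive", {
  set.seed(3)
  x <- matrix(rnorm(200), 40, 5)
  m <- pca_fit(x)
  for (j in seq_len(ncol(m$loadings))) {
    v <- m$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("variance-target retention keeps the smallest sufficient set", {
  set.seed(4)
  x <- cbind(rnorm(50, sd = 10), rnorm(50, sd = 3), rnorm(50, sd = 0.1))
  m <- pca_fit(x, variance_target = 0.95)
  expect_equal(ncol(m$loadings),
               which(cumsum(m$all_variances) / sum(m$all_variances) >= 0.95)[1])
})

test_that("LDA separates well-separated 1-D clusters perfectly", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c("a", "a", "b", "b")
  m <- lda_fit(x, lab)
  expect_equal(lda_predict(m, x), lab)
})

test_that("LDA direction matches the closed-form 2x2 solution", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40), 20, 2),
             sweep(matrix(rnorm(40), 20, 2), 2, c(3, 1), `+`))
  lab <- rep(c("a", "b"), each = 20)
  m <- lda_fit(x, lab)
  # oracle: explicit pooled scatter and hand-coded 2x2 inverse
  x1 <- x[1:20, ]; x2 <- x[21:40, ]
  c1 <- sweep(x1, 2, colMeans(x1)); c2 <- sweep(x2, 2, colMeans(x2))
  S <- (t(c1) %*% c1 + t(c2) %*% c2) / 38
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det_s
  w0 <- Sinv %*% (colMeans(x1) - colMeans(x2))
  cosang <- abs(sum(m$direction * w0) / sqrt(sum(w0^2)))
  expect_equal(cosang, 1, tolerance = 1e-10)
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(6)
  x <- rbind(matrix(rnorm(60), 30, 2),
             sweep(matrix(rnorm(60), 30, 2), 2, c(2, -1), `+`))
  lab <- rep(c("a", "b"), each = 30)
  m <- lda_fit(x, lab)
  ref <- MASS::lda(x, grouping = lab)
  cosang <- abs(sum(m$direction * ref$scaling) / sqrt(sum(ref$scaling^2)))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("swapping class labels negates the direction, not the predictions", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40), 20, 2),
             sweep(matrix(rnorm(40), 20, 2), 2, c(4, 0), `+`))
  lab <- rep(c("a", "b"), each = 20)
  m1 <- lda_fit(x, lab)
  m2 <- lda_fit(x, ifelse(lab == "a", "b", "a"))
  # classes sort identically, so orientation to "class 1 projects higher"
  # flips the fitted direction when the labels flip
  expect_equal(m2$direction, -m1$direction, tolerance = 1e-10)
  p1 <- lda_predict(m1, x)
  p2 <- lda_predict(m2, x)
  expect_equal(p2, ifelse(p1 == "a", "b", "a"))
})

test_that("cross-validation contracts: separable limit, duplication, kfold", {
  cfg <- small_cfg(seed = 13, nd = 10, nn = 10, noise_sd = 0.01,
                   mu_specific = 150, sd_specific = 5)
  coh <- generate_cohort(cfg)
  resp <- generate_responses(coh, receptor_panel(), cfg)
  rep_loo <- crossvalidate(resp, coh$group, "loo")
  expect_equal(rep_loo$accuracy, 100)
  # duplicating every sample leaves resubstitution accuracy unchanged
  d <- default_data(seed = 14)
  r1 <- crossvalidate(d$responses, d$cohort$group, "resubstitution")
  dup <- rbind(d$responses, d$responses)
  r2 <- crossvalidate(dup, rep(as.character(d$cohort$group), 2),
                      "resubstitution")
  expect_equal(r2$accuracy, r1$accuracy)
  # kfold is deterministic given the seed and stratified
  k1 <- crossvalidate(d$responses, d$cohort$group, "kfold", k = 5, seed = 3)
  k2 <- crossvalidate(d$responses, d$cohort$group, "kfold", k = 5, seed = 3)
  expect_identical(k1$confusion, k2$confusion)
})

test_that("default-generator LOO accuracy sits in the plausibility band", {
  accs <- vapply(1:20, function(s) {
    d <- default_data(seed = s)
    crossvalidate(d$responses, d$cohort$group, "loo")$accuracy
  }, 0)
  expect_gt(mean(accs), 78.9)
  expect_lt(mean(accs), 98.9)
})

test_that("export_scores: plumbing, degenerate PC2, PC1-FBG correlation", {
  # 1-D embedded data -> PC2 scores all ~0
  set.seed(8)
  x1 <- outer(rnorm(15), c(2, 1, 0.5))
  es1 <- export_scores(x1, rep(c("a", "b"), length.out = 15))
  expect_lt(max(abs(es1$scores$PC2)), 1e-10)
  # full default run: row count, CSV, |r(PC1, FBG)| clearly nonzero
  d <- default_data(seed = 15)
  csv <- tempfile(fileext = ".csv")
  plt <- tempfile(fileext = ".png")
  es <- export_scores(d$responses, d$cohort$group, fbg = d$cohort$fbg,
                      file_csv = csv, file_plot = plt)
  expect_equal(nrow(es$scores), 90L)
  expect_true(file.exists(csv))
  expect_equal(nrow(read.csv(csv)), 90L)
  expect_true(any(file.exists(c(plt, sub("png$", "pdf", plt)))))
  expect_gt(abs(es$pc1_fbg$r), 0.3)
  unlink(c(csv, plt, sub("png$", "pdf", plt)))
})
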