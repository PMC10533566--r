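# DAF, norms, t-tests, correlation, RSD, confusion metrics.

test_that("euclidean_norm: basic identities and brute-force oracle", {
  expect_equal(euclidean_norm(rep(0, 36)), 0)
  expect_equal(euclidean_norm(c(3, 4, rep(0, 34))), 5)
  set.seed(1)
  x <- runif(36, 0, 200)
  acc <- 0
  for (v in x) acc <- acc + v * v   # independent summation
  expect_equal(euclidean_norm(x), sqrt(acc), tolerance = 1e-12)
  expect_error(euclidean_norm(numeric(0)), "empty")
})

test_that("DAF equals the hand-computed ANOVA ratio and the F statistic", {
  # hand oracle: groups {1,2,3} and {7,8,9} -> MSB 54, MSW 1
  expect_equal(daf(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3)), 54)
  # identical group means -> 0 between-group variance
  expect_equal(daf(c(1, 2, 3, 2, 1, 3), rep(c("a", "b"), each = 3)), 0)
  # location invariance
  set.seed(2)
  x <- rnorm(24); lab <- rep(c("g1", "g2", "g3"), each = 8)
  expect_equal(daf(x + 17.3, lab), daf(x, lab), tolerance = 1e-12)
  # equals the classical one-way ANOVA F on random instances
  for (i in 1:5) {
    set.seed(100 + i)
    y <- rnorm(30, mean = rep(c(0, 1, 3), each = 10))
    g <- factor(rep(c("a", "b", "c"), each = 10))
    f_ref <- unname(summary(aov(y ~ g))[[1]][["F value"]][1])
    expect_equal(daf(y, g), f_ref, tolerance = 1e-10)
  }
  # zero within-group spread with separated means
  expect_equal(daf(c(1, 1, 2, 2), c("a", "a", "b", "b")), Inf)
  expect_error(daf(c(1, 2, 3), c("a", "a", "b")), "degenerate-group")
})

test_that("multivariate DAF is the df-normalised scatter-trace ratio", {
  set.seed(3)
  x <- matrix(rnorm(40), 20, 2)
  x[11:20, ] <- x[11:20, ] + 2
  lab <- rep(c("a", "b"), each = 10)
  # oracle: sum of per-column ANOVA sums of squares
  ssb <- 0; ssw <- 0
  for (j in 1:2) {
    grand <- mean(x[, j])
    for (g in c("a", "b")) {
      xi <- x[lab == g, j]
      ssb <- ssb + length(xi) * (mean(xi) - grand)^2
      ssw <- ssw + sum((xi - mean(xi))^2)
    }
  }
  expect_equal(daf(x, lab), (ssb / 1) / (ssw / 18), tolerance = 1e-12)
})

test_that("rank_conditions orders by DAF with lexicographic tie-break", {
  set.seed(4)
  lab <- rep(c("a", "b"), each = 20)
  make_cond <- function(gap) c(rnorm(20, 0), rnorm(20, gap))
  vals <- list(`set 1` = make_cond(1), `set 2` = make_cond(4),
               `set 3` = make_cond(1.5), `set 4` = make_cond(0.5))
  rk <- rank_conditions(vals, lab)
  expect_equal(rk$condition_id[1], "set 2")
  expect_true(all(diff(rk$daf) <= 0))
  # identical data in every condition -> equal DAF, lexicographic order
  same <- list(b = c(1, 2, 6, 7), a = c(1, 2, 6, 7))
  rk2 <- rank_conditions(same, c("x", "x", "y", "y"))
  expect_equal(rk2$daf[1], rk2$daf[2])
  expect_equal(rk2$condition_id, c("a", "b"))
  # single condition passes through
  expect_equal(nrow(rank_conditions(list(only = c(1, 2, 6, 7)),
                                    c("x", "x", "y", "y"))), 1L)
})

test_that("two-sample t-test: degenerate cases and published summaries", {
  res <- two_sample_ttest(5, 1, 10, 5, 1, 10)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(two_sample_ttest(5, 0, 10, 5, 0, 10)$p, 1)
  expect_equal(two_sample_ttest(6, 0, 10, 5, 0, 10)$t, Inf)
  # the published group norm summaries separate at p < 0.001
  tt <- two_sample_ttest(358.31, 27.98, 45, 328.47, 31.60, 45)
  expect_lt(tt$p, 0.001)
  expect_equal(tt$df, 88)
})

test_that("t-test on raw samples agrees with stats::t.test (both variants)", {
  set.seed(5)
  x <- rnorm(20, 1, 1); y <- rnorm(25, 0, 2)
  mine <- two_sample_ttest(x = x, y = y, variant = "pooled")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  mine_w <- two_sample_ttest(x = x, y = y, variant = "welch")
  ref_w <- t.test(x, y)
  expect_equal(mine_w$t, unname(ref_w$statistic), tolerance = 1e-12)
  expect_equal(mine_w$df, unname(ref_w$parameter), tolerance = 1e-10)
  expect_equal(mine_w$p, ref_w$p.value, tolerance = 1e-12)
})

test_that("threshold classification is strictly greater-than", {
  expect_equal(threshold_classify(c(343.40, 343.38), 343.39),
               c("diabetic", "nondiabetic"))
  expect_equal(threshold_classify(rep(343.39, 3), 343.39),
               rep("nondiabetic", 3))
  expect_error(threshold_classify(1:3, NA), "finite")
})

test_that("grand-mean threshold accuracy matches the normal-model closed form", {
  # closed form under the two configured norm distributions
  cfg <- generator_config()
  thr <- (cfg$norm_mean_d + cfg$norm_mean_nd) / 2
  acc_cf <- 100 * (pnorm((cfg$norm_mean_d - thr) / cfg$norm_sd_d) +
                   pnorm((thr - cfg$norm_mean_nd) / cfg$norm_sd_nd)) / 2
  # Monte-Carlo oracle straight from the two normal laws
  set.seed(6)
  n <- 5e5
  nd <- rnorm(n, cfg$norm_mean_d, cfg$norm_sd_d)
  nn <- rnorm(n, cfg$norm_mean_nd, cfg$norm_sd_nd)
  acc_mc <- 100 * (mean(nd > thr) + mean(nn <= thr)) / 2
  expect_equal(acc_mc, acc_cf, tolerance = 0.5 / acc_cf)
  # the generator reproduces it through the full pipeline
  big <- generator_config(n_diabetic = 3000, n_nondiabetic = 3000, seed = 7)
  coh <- generate_cohort(big)
  norms <- total_responses(generate_responses(coh, receptor_panel(), big))
  pred <- threshold_classify(norms, thr)
  acc_gen <- 100 * mean(pred == coh$group)
  expect_equal(acc_gen, acc_cf, tolerance = 1.5 / acc_cf)
})

test_that("pearson: exact cases, hand covariance oracle, error handling", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  # hand oracle for (1,2,3) vs (1,3,2): cov 0.5, sds 1 -> r = 0.5
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2))$r, 0.5, tolerance = 1e-12)
  # invariance under positive affine maps; sign flip under negation
  set.seed(8)
  a <- rnorm(30); b <- rnorm(30) + a
  expect_equal(pearson(3 * a + 2, 0.5 * b - 7)$r, pearson(a, b)$r,
               tolerance = 1e-12)
  expect_equal(pearson(-a, b)$r, -pearson(a, b)$r, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), ">= 3")
})

test_that("RSD: exact cases and guards", {
  expect_equal(rsd_percent(c(9, 10, 11)), 10)
  expect_equal(rsd_percent(rep(3.2, 6)), 0)
  expect_error(rsd_percent(c(-1, 1)), "zero mean")
  expect_error(rsd_percent(5), ">= 2")
})

test_that("confusion metrics: published outcome, extremes, class identity", {
  cm <- matrix(c(41, 6, 4, 39), 2, 2,
               dimnames = list(c("diabetic", "nondiabetic"),
                               c("diabetic", "nondiabetic")))
  rep <- confusion_metrics(cm)
  expect_equal(round_half_up(rep$accuracy), 88.9)
  expect_equal(round_half_up(rep$error_rate), 11.1)
  expect_equal(round_half_up(rep$sensitivity[["diabetic"]]), 91.1)
  expect_equal(round_half_up(rep$sensitivity[["nondiabetic"]]), 86.7)
  expect_equal(rep$specificity[["nondiabetic"]], rep$sensitivity[["diabetic"]])
  expect_equal(rep$accuracy + rep$error_rate, 100)
  perfect <- confusion_metrics(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$error_rate, 0)
  wrong <- confusion_metrics(matrix(c(0, 10, 10, 0), 2, 2))
  expect_equal(wrong$accuracy, 0)
  expect_true(all(wrong$sensitivity == 0))
  # two-class identity holds for random confusion matrices
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(rpois(4, 10) + 1, 2, 2)
    r <- confusion_metrics(m)
    expect_equal(unname(r$sensitivity[1]), unname(r$specificity[2]))
    expect_equal(unname(r$sensitivity[2]), unname(r$specificity[1]))
  }
})

test_that("total_response_summary: balanced grand mean and t-test wiring", {
  d <- default_data(seed = 12)
  trs <- total_response_summary(d$responses, d$cohort$group)
  expect_equal(trs$grand_mean, mean(trs$group_stats$mean))  # balanced groups
  expect_equal(length(trs$norms), 90L)
  expect_true(trs$p < 0.05)
})
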