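# Univariate chemometrics: the discrimination ability function (DAF),
# total-response norms, threshold classification, summary t-tests, Pearson
# correlation, replicate RSD and confusion metrics.

#' Euclidean norm of a response vector
#'
#' The "total response" of a sample: the square root of the sum of squared
#' features of its 36-element response vector.
#'
#' @param x Finite numeric vector, length >= 1.
#' @return Non-negative scalar.
#' @export
#' @examples
#' euclidean_norm(c(3, 4))  # 5
euclidean_norm <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("argument error: empty vector")
  if (any(!is.finite(x))) stop("argument error: non-finite values")
  sqrt(sum(x^2))
}

#' Row-wise total responses of a response matrix
#' @param responses n x 36 numeric matrix.
#' @return Numeric vector of per-sample Euclidean norms.
#' @export
total_responses <- function(responses) {
  m <- unclass(as.matrix(responses))
  sqrt(rowSums(m^2))
}

#' Discrimination ability function (DAF)
#'
#' The ratio of inter-group to intra-group variance used to score
#' experimental conditions: for scalar responses this is the one-way
#' ANOVA ratio MSB/MSW (between-group over within-group mean square); for
#' multivariate responses the trace of the between-group scatter over the
#' trace of the within-group scatter with the same degree-of-freedom
#' normalisation.  Higher values mean better-separated groups.
#'
#' @param values Numeric vector (one scalar per sample) or matrix (one row
#'   per sample).
#' @param labels Group label per sample; >= 2 groups, each with >= 2
#'   samples.
#' @return Non-negative scalar; `Inf` when groups differ but there is no
#'   within-group spread.
#' @export
#' @examples
#' daf(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))  # 54
daf <- function(values, labels) {
  labels <- as.character(labels)
  x <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1)
  if (nrow(x) != length(labels)) stop("values and labels lengths differ")
  groups <- split(seq_len(nrow(x)), labels)
  if (length(groups) < 2L) stop("degenerate-group error: need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("degenerate-group error: every group needs >= 2 samples")
  }
  n <- nrow(x); k <- length(groups)
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (idx in groups) {
    gx <- x[idx, , drop = FALSE]
    gm <- colMeans(gx)
    ssb <- ssb + length(idx) * sum((gm - grand)^2)
    ssw <- ssw + sum(sweep(gx, 2, gm)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  if (msw == 0) {
    if (msb == 0) return(0)
    return(Inf)
  }
  msb / msw
}

#' Rank experimental conditions by DAF
#'
#' Computes the DAF for each condition's responses and orders conditions
#' from most to least discriminating; ties break lexicographically by
#' condition id, so rankings are deterministic.
#'
#' @param condition_values Named list: one numeric vector/matrix of
#'   responses per condition.
#' @param condition_labels Named list of group labels per condition, or a
#'   single vector recycled for all conditions.
#' @return Data frame with `condition_id`, `daf`, `n`, sorted by
#'   decreasing DAF.
#' @export
rank_conditions <- function(condition_values, condition_labels) {
  ids <- names(condition_values)
  if (is.null(ids) || any(ids == "")) stop("conditions must be named")
  if (!is.list(condition_labels)) {
    condition_labels <- stats::setNames(
      rep(list(condition_labels), length(ids)), ids)
  }
  dafs <- vapply(ids, function(id) {
    daf(condition_values[[id]], condition_labels[[id]])
  }, 0)
  ns <- vapply(ids, function(id) {
    v <- condition_values[[id]]
    if (is.matrix(v)) nrow(v) else length(v)
  }, 0L)
  out <- data.frame(condition_id = ids, daf = dafs, n = ns,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$daf, out$condition_id), , drop = FALSE]
}

#' Two-independent-sample t-test from group summaries or raw samples
#'
#' The pooled-variance (Student) test by default, Welch's by flag.  Accepts
#' either summary statistics (mean, SD, n per group) or raw sample vectors
#' through `x` / `y`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @param x,y Optional raw samples; when given, summaries are computed from
#'   them.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided), `variant`.
#' @export
#' @examples
#' two_sample_ttest(358.31, 27.98, 45, 328.47, 31.60, 45)$p  # < 0.001
two_sample_ttest <- function(mean1, sd1, n1, mean2, sd2, n2,
                             variant = c("pooled", "welch"),
                             x = NULL, y = NULL) {
  variant <- match.arg(variant)
  if (!is.null(x) || !is.null(y)) {
    stopifnot(!is.null(x), !is.null(y))
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("argument error: each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("argument error: SDs must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, variant = variant))
    }
    return(list(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2, p = 0,
                variant = variant))
  }
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), variant = variant)
}

#' Classify samples by their total response against a threshold
#'
#' Samples whose norm exceeds the threshold are called diabetic; ties and
#' smaller values are called non-diabetic (the rule is strictly "greater
#' than").
#'
#' @param norms Numeric vector of per-sample total responses.
#' @param threshold Finite scalar (typically the grand mean norm).
#' @return Character vector of `"diabetic"` / `"nondiabetic"` labels.
#' @export
#' @examples
#' threshold_classify(c(343.40, 343.38), 343.39)
threshold_classify <- function(norms, threshold) {
  if (!is.finite(threshold)) stop("argument error: threshold must be finite")
  ifelse(norms > threshold, "diabetic", "nondiabetic")
}

#' Pearson correlation with its two-sided p-value
#'
#' The p-value uses the exact t transform `t = r sqrt((n-2)/(1-r^2))` on
#' n - 2 degrees of freedom (as [stats::cor.test()] does; that routine is
#' used as the backend).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r`, `p`, `n`.
#' @export
#' @examples
#' pearson(1:10, 2 * (1:10) + 1)$r  # 1
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("argument error: lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("argument error: need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation error: constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Relative standard deviation (RSD %) of replicate measurements
#'
#' `100 * sd(x) / mean(x)` with the n-1 SD denominator; the reproducibility
#' statistic for replicate sensor runs.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd_percent(c(9, 10, 11))  # 10
rsd_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("argument error: RSD needs >= 2 replicates")
  m <- mean(values)
  if (m == 0) stop("undefined-RSD error: zero mean")
  100 * stats::sd(values) / m
}

#' Classification metrics from a 2 x 2 confusion matrix
#'
#' Rows are truth, columns are predictions, both ordered
#' (diabetic, nondiabetic).  Returns exact (unrounded) percentages;
#' rounding half away from zero to one decimal happens only in the print
#' method / reporting layer.  In the two-class case each class's
#' specificity equals the other class's sensitivity.
#'
#' @param confusion 2 x 2 non-negative integer matrix with total > 0.
#' @return Object of class `classification_report`: `confusion`, `n`,
#'   `accuracy`, `error_rate`, `sensitivity` and `specificity` (named per
#'   class), all percentages.
#' @export
#' @examples
#' cm <- matrix(c(41, 6, 4, 39), 2, 2,
#'              dimnames = list(c("diabetic", "nondiabetic"),
#'                              c("diabetic", "nondiabetic")))
#' confusion_metrics(cm)
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!identical(dim(confusion), c(2L, 2L)) || any(confusion < 0)) {
    stop("argument error: confusion must be a non-negative 2 x 2 matrix")
  }
  n <- sum(confusion)
  if (n == 0) stop("argument error: empty confusion matrix")
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- c("diabetic", "nondiabetic")
  truth_tot <- rowSums(confusion)
  sens <- ifelse(truth_tot > 0, 100 * diag(confusion) / truth_tot, NA_real_)
  names(sens) <- classes
  spec <- rev(sens)
  names(spec) <- classes
  acc <- 100 * sum(diag(confusion)) / n
  structure(list(
    confusion = confusion, n = n,
    accuracy = acc, error_rate = 100 - acc,
    sensitivity = sens, specificity = spec,
    undefined_classes = classes[truth_tot == 0]
  ), class = "classification_report")
}

#' Round half away from zero (reporting convention for percentages)
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (n =", x$n, ")\n")
  print(x$confusion)
  cat(sprintf("Accuracy: %.1f%%  Error rate: %.1f%%\n",
              round_half_up(x$accuracy), round_half_up(x$error_rate)))
  for (cl in names(x$sensitivity)) {
    cat(sprintf("  %s: sensitivity %.1f%%, specificity %.1f%%\n", cl,
                round_half_up(x$sensitivity[[cl]]),
                round_half_up(x$specificity[[cl]])))
  }
  invisible(x)
}

#' Total-response summary: group norms, grand mean and t-test
#'
#' Computes per-sample Euclidean norms, per-group means and SDs, the grand
#' mean (the default threshold of the norm classifier), and the pooled
#' two-sample t-test between the groups.
#'
#' @param responses n x 36 response matrix.
#' @param groups Group label per row ("diabetic"/"nondiabetic").
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return List of class `total_response_summary`: `norms`, `group_stats`
#'   (data frame), `grand_mean`, `t`, `df`, `p`.
#' @export
total_response_summary <- function(responses, groups,
                                   variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  norms <- total_responses(responses)
  groups <- as.character(groups)
  gs <- split(norms, groups)
  stats_df <- data.frame(
    group = names(gs),
    n = lengths(gs),
    mean = vapply(gs, mean, 0),
    sd = vapply(gs, stats::sd, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(norms = norms, group_stats = stats_df,
              grand_mean = mean(norms), t = NA_real_, df = NA_real_,
              p = NA_real_)
  if (length(gs) == 2L && all(lengths(gs) >= 2L)) {
    tt <- two_sample_ttest(stats_df$mean[1], stats_df$sd[1], stats_df$n[1],
                           stats_df$mean[2], stats_df$sd[2], stats_df$n[2],
                           variant = variant)
    out$t <- tt$t; out$df <- tt$df; out$p <- tt$p
  }
  class(out) <- "total_response_summary"
  out
}
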