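# Two-class Fisher linear discriminant, written out explicitly so the
# decision rule (direction, threshold, priors) is fully transparent.

#' Fit a two-class Fisher linear discriminant
#'
#' The discriminant direction is `solve(Sw, mu1 - mu2)` where `Sw` is the
#' pooled within-class scatter (covariance) matrix and `mu1`, `mu2` the
#' class means; a ridge term `ridge * I` stabilises `Sw` when it is
#' (near-)singular.  The direction is normalised to unit length and
#' oriented so class 1 (first sorted label) projects higher.  The decision
#' threshold sits at the midpoint of the projected class means, shifted by
#' the log prior odds scaled by the pooled projected variance (the
#' Gaussian-optimal rule; with equal priors this is the plain midpoint).
#'
#' @param scores Numeric matrix (samples x features, typically PC scores).
#' @param labels Two-class label per row, each class with >= 2 samples.
#' @param priors Named class priors; default equal.
#' @param ridge Ridge added to `Sw` when singular (default 1e-8 x mean
#'   diagonal).
#' @return Object of class `lda_model`: `direction` (unit vector),
#'   `classes`, `projected_means`, `threshold`, `priors`.
#' @export
lda_fit <- function(scores, labels, priors = NULL, ridge = NULL) {
  x <- as.matrix(unclass(scores))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("label error: exactly 2 classes required, got ", length(classes))
  }
  idx1 <- labels == classes[1]; idx2 <- labels == classes[2]
  if (sum(idx1) < 2 || sum(idx2) < 2) {
    stop("label error: each class needs >= 2 samples")
  }
  x1 <- x[idx1, , drop = FALSE]; x2 <- x[idx2, , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  sw <- (crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x2, 2, mu2))) /
    (n1 + n2 - 2)
  if (is.null(ridge)) ridge <- 1e-8 * mean(diag(sw))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-8
  w <- tryCatch(solve(sw, mu1 - mu2),
                error = function(e) solve(sw + diag(ridge, ncol(x)), mu1 - mu2))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("degenerate discriminant: identical class means")
  w <- w / nw
  p1 <- drop(x1 %*% w); p2 <- drop(x2 %*% w)
  if (mean(p1) < mean(p2)) { w <- -w; p1 <- -p1; p2 <- -p2 }
  if (is.null(priors)) {
    priors <- stats::setNames(c(0.5, 0.5), classes)
  } else {
    priors <- priors[classes] / sum(priors[classes])
  }
  m1 <- mean(p1); m2 <- mean(p2)
  s2 <- (sum((p1 - m1)^2) + sum((p2 - m2)^2)) / (n1 + n2 - 2)
  thr <- (m1 + m2) / 2
  if (m1 != m2 && s2 > 0) {
    thr <- thr - s2 * log(priors[[1]] / priors[[2]]) / (m1 - m2)
  }
  structure(list(direction = w, classes = classes,
                 projected_means = stats::setNames(c(m1, m2), classes),
                 threshold = thr, priors = priors),
            class = "lda_model")
}

#' Predict class labels with a fitted LDA model
#' @param model An `lda_model`.
#' @param scores Matrix in the same feature space the model was fitted on.
#' @return Character vector of predicted class labels.
#' @export
lda_predict <- function(model, scores) {
  p <- drop(as.matrix(unclass(scores)) %*% model$direction)
  ifelse(p > model$threshold, model$classes[1], model$classes[2])
}
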