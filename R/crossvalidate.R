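# Cross-validated PCA-LDA classification.

#' Cross-validate the PCA-LDA classifier
#'
#' Per training fold: fit PCA on the training rows only, keep the smallest
#' set of leading components reaching `variance_target` cumulative
#' variance, fit the Fisher discriminant on the training scores, then
#' classify the held-out rows.  Fitting the PCA inside each fold avoids
#' information leakage from test to training data; resubstitution
#' (fit and evaluate on all rows) is available for comparison with
#' analyses that fit the decomposition once.
#'
#' @param x n x p response matrix.
#' @param labels Two-class label per row.
#' @param scheme `"loo"` (leave-one-out, default), `"kfold"` or
#'   `"resubstitution"`.  loo and resubstitution are deterministic; kfold
#'   is deterministic given `seed` (folds are stratified by class).
#' @param k Number of folds for `"kfold"` (default 5).
#' @param seed Integer seed for kfold shuffling.
#' @param variance_target Cumulative explained-variance fraction for
#'   per-fold component retention (default 0.95).
#' @return A `classification_report` (see [confusion_metrics()]) with the
#'   pooled confusion matrix, plus `predictions` and `scheme` fields.
#' @export
crossvalidate <- function(x, labels,
                          scheme = c("loo", "kfold", "resubstitution"),
                          k = 5L, seed = 1L, variance_target = 0.95) {
  scheme <- match.arg(scheme)
  x <- as.matrix(unclass(x))
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("label error: exactly 2 classes required")
  n <- nrow(x)

  folds <- switch(scheme,
    loo = as.list(seq_len(n)),
    resubstitution = list(seq_len(n)),
    kfold = stratified_folds(labels, k, seed)
  )

  preds <- character(n)
  for (fold in folds) {
    train <- if (scheme == "resubstitution") seq_len(n) else setdiff(seq_len(n), fold)
    if (length(unique(labels[train])) < 2L) {
      stop("stratification error: a training fold lost a class")
    }
    pca <- pca_fit(x[train, , drop = FALSE], variance_target = variance_target)
    tr_scores <- pca_transform(pca, x[train, , drop = FALSE])
    model <- lda_fit(tr_scores, labels[train])
    te_scores <- pca_transform(pca, x[fold, , drop = FALSE])
    preds[fold] <- lda_predict(model, te_scores)
  }

  cm <- table(factor(labels, levels = classes),
              factor(preds, levels = classes))
  cm <- matrix(as.integer(cm), 2, 2, dimnames = list(classes, classes))
  rep <- confusion_metrics(cm)
  rep$predictions <- preds
  rep$scheme <- scheme
  rep
}

# Deterministic stratified k-fold assignment.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  assign <- integer(n)
  set.seed(as.integer(seed))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(assign == f))
}
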