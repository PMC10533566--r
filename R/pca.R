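# Principal component analysis with a fixed sign convention.

#' Fit a PCA model to a response matrix
#'
#' Mean-centred (unscaled) PCA via the singular value decomposition
#' ([stats::prcomp()]).  Components are ordered by explained variance and
#' each loading vector's sign is fixed so that its largest-magnitude
#' element is positive, making scores reproducible across runs and
#' platforms.
#'
#' @param x Numeric matrix, n >= 2 rows, no missing values.
#' @param n_components Number of components to keep (default: all).
#' @param variance_target If given (e.g. 0.95), keep the smallest set of
#'   leading components reaching this cumulative explained-variance
#'   fraction; overrides `n_components`.
#' @return Object of class `pca_model`: `center`, `loadings` (columns are
#'   orthonormal component vectors), `variance` (per component),
#'   `cum_var_pct` (cumulative percentages of total variance),
#'   `total_variance`.
#' @export
pca_fit <- function(x, n_components = NULL, variance_target = NULL) {
  x <- as.matrix(unclass(x))
  if (nrow(x) < 2L) stop("data error: PCA needs at least 2 rows")
  if (anyNA(x)) stop("data error: missing values")
  total_var <- sum(apply(x, 2, stats::var))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pr$sdev^2
  if (total_var == 0) {
    warning("zero-variance (constant) matrix; all components degenerate")
  }
  # sign convention: largest-|loading| element positive
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(pr$rotation, 2, flip, `*`)
  cum_pct <- if (total_var > 0) 100 * cumsum(vars) / total_var else
    rep(0, length(vars))
  k <- length(vars)
  if (!is.null(variance_target)) {
    k <- which(cum_pct >= 100 * variance_target - 1e-9)[1]
    if (is.na(k)) k <- length(vars)
  } else if (!is.null(n_components)) {
    k <- min(n_components, length(vars))
  }
  structure(list(
    center = pr$center,
    loadings = load[, seq_len(k), drop = FALSE],
    variance = vars[seq_len(k)],
    cum_var_pct = cum_pct[seq_len(k)],
    total_variance = total_var,
    all_variances = vars
  ), class = "pca_model")
}

#' Project data onto a fitted PCA model
#' @param model A `pca_model`.
#' @param x Matrix with the same columns the model was fitted on.
#' @return Score matrix (n x k).
#' @export
pca_transform <- function(model, x) {
  x <- as.matrix(unclass(x))
  sweep(x, 2, model$center) %*% model$loadings
}

#' Reconstruct (centred) data from scores
#' @param model A `pca_model`.
#' @param scores n x k score matrix.
#' @return Reconstruction in the original feature space.
#' @export
pca_inverse <- function(model, scores) {
  sweep(scores %*% t(model$loadings), 2, model$center, `+`)
}
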