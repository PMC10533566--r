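# Synthetic 36-feature response matrices.
#
# Latent-severity model.  Each participant's fasting blood glucose drives
# the panel response:
#   * receptors not responsive to the participant's group emit only an
#     absolute-Gaussian noise floor (exactly zero when noise_sd = 0);
#   * group-shared receptors (S2, S9) draw magnitudes around mu_shared;
#   * the FBG-linked receptors draw magnitudes whose latent component is
#     bivariate-normal with (standardised) FBG at the configured
#     correlation: TMA-AgNPs (S10) against FBG directly, MR+TBOH (S5)
#     against the binned-FBG representative value;
#   * group-specific receptors (S3 non-diabetic; S7, S8, S12 diabetic) are
#     gated by a logistic severity term in FBG, so borderline participants
#     show a weak differential pattern (the saturating-response part of the
#     model) — their magnitude is lognormal, hence strictly positive for
#     the responsive group;
#   * finally each row's free receptors (everything responsive except S5
#     and S10) are rescaled so the row's Euclidean norm equals a draw from
#     the configured per-group norm distribution.  S5/S10 are excluded
#     from this calibration so their FBG correlation survives exactly.
# Magnitudes are expanded to 36 non-negative channel features through each
# receptor's unit channel-weight vector.

#' Generate a synthetic response matrix for a cohort
#'
#' @param cohort A cohort from [generate_cohort()] (or any data frame with
#'   `id`, `group`, `fbg` columns).
#' @param panel A 12-receptor panel, see [receptor_panel()].
#' @param config A [generator_config()].
#' @return An n x 36 numeric matrix (class `salisense_responses`), columns
#'   `S1_R` ... `S12_B` on the 0-255 scale, row names the participant ids.
#' @export
#' @examples
#' cfg <- generator_config(n_diabetic = 4, n_nondiabetic = 4)
#' coh <- generate_cohort(cfg)
#' resp <- generate_responses(coh, receptor_panel(), cfg)
#' dim(resp)
generate_responses <- function(cohort, panel = receptor_panel(),
                               config = generator_config()) {
  validate_panel(panel)
  stopifnot(inherits(config, "generator_config"))
  if (nrow(cohort) == 0L) stop("cohort must be non-empty")
  panel <- panel[order(panel$index), ]
  set.seed(stage_seed(config, "responses"))

  n <- nrow(cohort)
  group <- as.character(cohort$group)
  fbg <- cohort$fbg

  z_fbg <- standardise(fbg)
  z_bin <- standardise(fbg_binned(fbg, config))
  sev <- (fbg - config$fbg_pivot) / config$fbg_scale

  w <- panel_weights(panel)
  active_w <- sqrt(rowSums(w^2)) > 0   # receptor contributes to the norm

  # Magnitudes, drawn receptor-by-receptor in panel order (fixed stream).
  m <- matrix(0, n, 12)
  for (s in 1:12) {
    eps <- stats::rnorm(n)
    resp_to <- panel$responsive_to[s]
    on <- is_responsive(resp_to, group)
    ms <- abs(eps) * config$noise_sd           # noise floor everywhere...
    if (any(on)) {                             # ...overridden when responsive
      link <- panel$fbg_link[s]
      if (link == "direct") {
        lat <- config$rho_tma * z_fbg + sqrt(1 - config$rho_tma^2) * eps
        ms_on <- pmax(0, config$mu_corr + config$sd_corr * lat)
      } else if (link == "binned") {
        lat <- config$rho_mr * z_bin + sqrt(1 - config$rho_mr^2) * eps
        ms_on <- pmax(0, config$mu_corr + config$sd_corr * lat)
      } else if (resp_to == "both") {
        ms_on <- pmax(0, config$mu_shared + config$sd_shared * eps)
      } else {
        # group-specific: logistic severity gate x lognormal magnitude
        gate <- if (resp_to == "diabetic") stats::plogis(sev) else stats::plogis(-sev)
        sigma <- config$sd_specific / config$mu_specific
        ms_on <- gate * config$mu_specific * exp(sigma * eps - sigma^2 / 2)
      }
      ms[on] <- ms_on[on]
    }
    m[, s] <- ms
  }

  # Per-row norm calibration on the free receptors.
  corr_idx <- which(panel$fbg_link != "none")
  target <- numeric(n)
  nm <- c(diabetic = config$norm_mean_d, nondiabetic = config$norm_mean_nd)
  ns <- c(diabetic = config$norm_sd_d, nondiabetic = config$norm_sd_nd)
  target <- stats::rnorm(n, nm[group], ns[group])
  for (i in seq_len(n)) {
    resp_on <- is_responsive(panel$responsive_to, group[i]) & active_w
    free <- resp_on & !(seq_len(12) %in% corr_idx)
    fixed2 <- sum((m[i, !free] * active_w[!free])^2)
    free2 <- max(target[i]^2 - fixed2, 0)
    free_norm2 <- sum(m[i, free]^2)
    if (any(free) && free_norm2 > 0) {
      m[i, free] <- m[i, free] * sqrt(free2 / free_norm2)
    }
  }

  out <- matrix(0, n, 36)
  for (s in 1:12) {
    out[, (3 * s - 2):(3 * s)] <- outer(m[, s], w[s, ])
  }
  out <- pmin(pmax(out, 0), 255)
  dimnames(out) <- list(cohort$id, response_colnames(panel))
  class(out) <- c("salisense_responses", class(out))
  out
}

standardise <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Summary response magnitude of one receptor
#'
#' The Euclidean norm of a receptor's three channel features per sample —
#' the scalar used for receptor-level correlation analyses.
#'
#' @param responses An n x 36 response matrix.
#' @param receptor Receptor index 1-12, or an `"S5"`-style label.
#' @return Numeric vector of length n.
#' @export
receptor_response <- function(responses, receptor) {
  if (is.character(receptor)) {
    receptor <- as.integer(sub("^S", "", receptor))
  }
  stopifnot(length(receptor) == 1L, receptor >= 1, receptor <= 12)
  block <- unclass(responses)[, (3 * receptor - 2):(3 * receptor), drop = FALSE]
  sqrt(rowSums(block^2))
}

#' Generate replicate measurements of one response row
#'
#' Emulates repeated fabrication/analysis of the same sample: each
#' replicate is the row scaled by an independent factor `1 + N(0, rsd/100)`
#' (the group's configured replicate RSD), plus an optional additive
#' per-element Gaussian component (`replicate_noise_sd`).  The RSD of the
#' replicate row norms converges to the configured value as k grows.
#'
#' @param response_row Numeric vector of length 36 (one sample's response).
#' @param k Number of replicates (>= 1).
#' @param config A [generator_config()].
#' @param group `"diabetic"` or `"nondiabetic"`; selects the RSD target.
#' @return A k x 36 matrix of non-negative replicate rows.
#' @export
generate_replicates <- function(response_row, k, config = generator_config(),
                                group = c("diabetic", "nondiabetic")) {
  group <- match.arg(group)
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1")
  }
  response_row <- as.numeric(response_row)
  set.seed(stage_seed(config, "replicates"))
  rsd <- if (group == "diabetic") config$replicate_rsd_d else config$replicate_rsd_nd
  fac <- pmax(1 + stats::rnorm(k, 0, rsd / 100), 0)
  out <- outer(fac, response_row)
  if (config$replicate_noise_sd > 0) {
    out <- out + matrix(stats::rnorm(k * length(response_row), 0,
                                     config$replicate_noise_sd),
                        k, length(response_row))
  }
  pmin(pmax(out, 0), 255)
}
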