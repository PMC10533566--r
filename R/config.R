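# Generator configuration.

#' Configuration for the synthetic cohort and response generator
#'
#' Defaults reproduce the study conditions of the clinical cohort the
#' generator emulates: 45 diabetic and 45 non-diabetic participants,
#' demographics matching the published table (means and observed ranges),
#' group total-response (Euclidean norm) distributions 358.31 (SD 27.98)
#' versus 328.47 (SD 31.60), receptor-FBG Pearson correlations 0.726
#' (MR+TBOH, on binned FBG) and 0.871 (TMA-AgNPs, direct), and replicate
#' relative standard deviations 6.03% / 6.71%.
#'
#' SDs for variables whose table prints only a mean and range (FBG, 2-h
#' postprandial glucose, TG, HbA1c) default to range/4, the conventional
#' range-based estimate.  Daily activity hours are not tabulated in the
#' source study; defaults (non-diabetic 2.0 h/day, diabetic 1.0 h/day, SD
#' 0.75) encode the qualitative claim that the diabetic group is less
#' mobile.
#'
#' Response-model parameters (`mu_shared`, `mu_corr`, `mu_specific`, their
#' SDs, `fbg_pivot`, `fbg_scale`, `noise_sd`) shape the latent-severity
#' model described in the methods vignette; their defaults are calibrated
#' so that group norm distributions, receptor-FBG correlations, replicate
#' RSDs and two-class separability jointly match the published statistics.
#'
#' @param n_diabetic,n_nondiabetic Group sizes (non-negative integers).
#' @param seed Integer seed; every generator stage derives its own stream
#'   from it so stages never perturb each other.
#' @param norm_mean_d,norm_sd_d,norm_mean_nd,norm_sd_nd Target mean/SD of
#'   the per-sample response-vector Euclidean norms per group.
#' @param rho_mr Pearson correlation between binned FBG and the MR+TBOH
#'   response magnitude.
#' @param rho_tma Pearson correlation between FBG and the TMA-AgNPs
#'   response magnitude.
#' @param replicate_rsd_d,replicate_rsd_nd Replicate norm RSD targets (%).
#' @param noise_sd SD (8-bit intensity units) of the absolute-Gaussian
#'   noise floor on non-responsive receptors.
#' @param replicate_noise_sd Additive per-element SD of replicate noise on
#'   top of the multiplicative component (default 0).
#' @param mu_shared,sd_shared Magnitude mean/SD for group-shared receptors
#'   (S2, S9).
#' @param mu_corr,sd_corr Magnitude mean/SD for the FBG-linked receptors
#'   (S5, S10).
#' @param mu_specific,sd_specific Magnitude scale/spread for group-specific
#'   receptors (S3, S7, S8, S12) before severity gating.
#' @param fbg_pivot,fbg_scale Centre (mg/dL) and scale of the logistic
#'   severity gate applied to group-specific receptors; the pivot sits in
#'   the FBG band where the study's misclassified borderline participants
#'   fall.
#' @param fbg_bins Breaks (mg/dL) of the FBG categories used for the
#'   MR+TBOH correlation; the open top bin is represented by the midpoint
#'   between its lower edge and the diabetic FBG range maximum.
#' @param demographics Nested list of per-group marginals; see defaults.
#' @return An object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_diabetic = 10, n_nondiabetic = 10, seed = 42)
#' cfg$norm_mean_d
generator_config <- function(n_diabetic = 45L,
                             n_nondiabetic = 45L,
                             seed = 1L,
                             norm_mean_d = 358.31, norm_sd_d = 27.98,
                             norm_mean_nd = 328.47, norm_sd_nd = 31.60,
                             rho_mr = 0.726, rho_tma = 0.871,
                             replicate_rsd_d = 6.03, replicate_rsd_nd = 6.71,
                             noise_sd = 17,
                             replicate_noise_sd = 0,
                             mu_shared = 130, sd_shared = 25,
                             mu_corr = 120, sd_corr = 22,
                             mu_specific = 32, sd_specific = 19,
                             fbg_pivot = 105, fbg_scale = 30,
                             fbg_bins = c(0, 100, 126, 200, Inf),
                             demographics = default_demographics()) {
  cfg <- list(
    n_diabetic = n_diabetic, n_nondiabetic = n_nondiabetic, seed = seed,
    norm_mean_d = norm_mean_d, norm_sd_d = norm_sd_d,
    norm_mean_nd = norm_mean_nd, norm_sd_nd = norm_sd_nd,
    rho_mr = rho_mr, rho_tma = rho_tma,
    replicate_rsd_d = replicate_rsd_d, replicate_rsd_nd = replicate_rsd_nd,
    noise_sd = noise_sd, replicate_noise_sd = replicate_noise_sd,
    mu_shared = mu_shared, sd_shared = sd_shared,
    mu_corr = mu_corr, sd_corr = sd_corr,
    mu_specific = mu_specific, sd_specific = sd_specific,
    fbg_pivot = fbg_pivot, fbg_scale = fbg_scale,
    fbg_bins = fbg_bins,
    demographics = demographics
  )
  validate_generator_config(cfg)
}

#' Published per-group demographic marginals
#'
#' Means and observed ranges follow the published cohort table; SDs in
#' parentheses there are used where printed (age), otherwise range/4.
#' @keywords internal
default_demographics <- function() {
  list(
    diabetic = list(
      fbg = list(mean = 146.37, lo = 84, hi = 287),
      glucose_2hpp = list(mean = 225.21, lo = 149, hi = 328),
      tg = list(mean = 184.62, lo = 81, hi = 477),
      hba1c = list(mean = 7.54, lo = 5.6, hi = 11.7),
      age = list(mean = 59.97, sd = 8.73, lo = 18, hi = 100),
      p_male = 26 / 45,
      activity = list(mean = 1.0, sd = 0.75, lo = 0, hi = 24)
    ),
    nondiabetic = list(
      fbg = list(mean = 96.39, lo = 82, hi = 109),
      glucose_2hpp = NULL,
      tg = list(mean = 168.72, lo = 52, hi = 625),
      hba1c = list(mean = 5.53, lo = 5.0, hi = 6.3),
      age = list(mean = 53.66, sd = 10.34, lo = 18, hi = 100),
      p_male = 20 / 45,
      activity = list(mean = 2.0, sd = 0.75, lo = 0, hi = 24)
    )
  )
}

validate_generator_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$n_diabetic) != 1L || length(cfg$n_nondiabetic) != 1L ||
      is.na(cfg$n_diabetic) || is.na(cfg$n_nondiabetic) ||
      cfg$n_diabetic < 0 || cfg$n_nondiabetic < 0 ||
      cfg$n_diabetic != round(cfg$n_diabetic) ||
      cfg$n_nondiabetic != round(cfg$n_nondiabetic)) {
    stop("group counts must be single non-negative integers")
  }
  sds <- c(cfg$norm_sd_d, cfg$norm_sd_nd, cfg$sd_shared, cfg$sd_corr,
           cfg$sd_specific)
  if (any(sds <= 0)) stop("all scale parameters (SDs) must be > 0")
  if (cfg$noise_sd < 0 || cfg$replicate_noise_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  if (abs(cfg$rho_mr) >= 1 || abs(cfg$rho_tma) >= 1) {
    stop("correlation parameters must lie in (-1, 1)")
  }
  if (cfg$replicate_rsd_d < 0 || cfg$replicate_rsd_nd < 0) {
    stop("replicate RSD targets must be non-negative")
  }
  if (length(cfg$fbg_bins) < 2 || is.unsorted(cfg$fbg_bins, strictly = TRUE)) {
    stop("fbg_bins must be strictly increasing breaks")
  }
  cfg$n_diabetic <- as.integer(cfg$n_diabetic)
  cfg$n_nondiabetic <- as.integer(cfg$n_nondiabetic)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "generator_config"
  cfg
}

# Stage-specific seeds: fixed offsets keep the cohort, response, replicate
# and pixel-noise streams independent of one another.
stage_seed <- function(cfg, stage = c("cohort", "responses", "replicates",
                                      "pixels")) {
  stage <- match.arg(stage)
  off <- c(cohort = 0L, responses = 100000L, replicates = 200000L,
           pixels = 300000L)[[stage]]
  as.integer(cfg$seed + off)
}

#' Representative values (midpoints) of the FBG bins
#'
#' Finite bins use their midpoints; the open top bin is represented by the
#' midpoint between its lower edge and the diabetic FBG range maximum.
#' @param cfg A [generator_config()].
#' @keywords internal
fbg_bin_mids <- function(cfg) {
  br <- cfg$fbg_bins
  hi_cap <- cfg$demographics$diabetic$fbg$hi
  lo <- br[-length(br)]
  hi <- br[-1]
  hi[is.infinite(hi)] <- hi_cap
  (lo + hi) / 2
}

# Map FBG values to their bin representative value.
fbg_binned <- function(fbg, cfg) {
  mids <- fbg_bin_mids(cfg)
  idx <- findInterval(fbg, cfg$fbg_bins, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > length(mids)] <- length(mids)
  mids[idx]
}
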