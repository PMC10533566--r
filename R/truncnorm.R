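# Truncated-normal helpers used by the cohort generator.
#
# Published demographic tables report a mean and an observed range per
# variable, not the parameters of an untruncated normal.  Sampling a normal
# truncated to the printed range shifts its mean away from the location
# parameter, so the generator solves for the location whose *truncated* mean
# equals the printed mean ("moment matching").

#' Mean of a normal distribution truncated to [lo, hi]
#'
#' @param location,sd Parameters of the parent normal.
#' @param lo,hi Truncation bounds.
#' @return The mean of the truncated distribution.
#' @keywords internal
truncnorm_mean <- function(location, sd, lo, hi) {
  a <- (lo - location) / sd
  b <- (hi - location) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  location + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Location parameter whose truncated mean equals a target
#'
#' @param target_mean Desired mean of the truncated distribution.
#' @inheritParams truncnorm_mean
#' @keywords internal
truncnorm_location_for_mean <- function(target_mean, sd, lo, hi) {
  if (target_mean <= lo || target_mean >= hi) {
    stop("target mean must lie strictly inside the truncation bounds")
  }
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - target_mean
  stats::uniroot(f, lower = target_mean - 6 * sd, upper = target_mean + 6 * sd,
                 tol = 1e-10)$root
}

#' Sample from a truncated normal by inverse-CDF
#'
#' Draws are a deterministic function of the RNG state (one uniform per
#' draw), which keeps the generator's streams reproducible.
#'
#' @param n Number of draws.
#' @inheritParams truncnorm_mean
#' @keywords internal
rnorm_trunc <- function(n, location, sd, lo, hi) {
  pa <- stats::pnorm(lo, location, sd)
  pb <- stats::pnorm(hi, location, sd)
  location + sd * stats::qnorm(stats::runif(n, pa, pb))
}

#' Sample a truncated normal whose sample space mean matches `target_mean`
#' @keywords internal
rnorm_trunc_matched <- function(n, target_mean, sd, lo, hi) {
  loc <- truncnorm_location_for_mean(target_mean, sd, lo, hi)
  rnorm_trunc(n, loc, sd, lo, hi)
}
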