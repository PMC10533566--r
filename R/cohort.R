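# Synthetic cohort generation.

#' Generate a synthetic clinical cohort
#'
#' Draws `n_diabetic + n_nondiabetic` participants whose marginals match
#' the published demographic table: FBG, 2-h postprandial glucose, TG and
#' HbA1c from truncated normals constrained to the printed ranges and
#' moment-matched so the *truncated* mean equals the printed mean; ages
#' from normals with the printed means and SDs truncated to [18, 100];
#' sex from the printed group sex ratios.  The same config and seed always
#' reproduce the identical cohort.
#'
#' @param config A [generator_config()].
#' @return A data frame of class `salisense_cohort` with columns `id`,
#'   `group` ("diabetic"/"nondiabetic"), `age`, `sex`, `fbg`,
#'   `glucose_2hpp` (NA for non-diabetic participants), `tg`, `hba1c`,
#'   `activity_hours`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_diabetic = 5, n_nondiabetic = 5))
#' table(coh$group)
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(stage_seed(config, "cohort"))
  d <- sample_group(config$n_diabetic, "diabetic",
                    config$demographics$diabetic, prefix = "D")
  nd <- sample_group(config$n_nondiabetic, "nondiabetic",
                     config$demographics$nondiabetic, prefix = "N")
  coh <- rbind(d, nd)
  rownames(coh) <- NULL
  class(coh) <- c("salisense_cohort", "data.frame")
  coh
}

sample_group <- function(n, group, dem, prefix) {
  n <- as.integer(n)
  if (n == 0L) {
    return(data.frame(id = character(), group = character(), age = numeric(),
                      sex = character(), fbg = numeric(),
                      glucose_2hpp = numeric(), tg = numeric(),
                      hba1c = numeric(), activity_hours = numeric(),
                      stringsAsFactors = FALSE))
  }
  range_sd <- function(m) (m$hi - m$lo) / 4  # conventional range-based SD
  draw <- function(m, sd = NULL) {
    if (is.null(sd)) sd <- range_sd(m)
    rnorm_trunc_matched(n, m$mean, sd, m$lo, m$hi)
  }
  fbg <- draw(dem$fbg)
  g2 <- if (is.null(dem$glucose_2hpp)) rep(NA_real_, n) else draw(dem$glucose_2hpp)
  tg <- draw(dem$tg)
  hba1c <- draw(dem$hba1c)
  age <- rnorm_trunc(n, dem$age$mean, dem$age$sd, dem$age$lo, dem$age$hi)
  sex <- ifelse(stats::runif(n) < dem$p_male, "male", "female")
  act <- rnorm_trunc(n, dem$activity$mean, dem$activity$sd,
                     dem$activity$lo, dem$activity$hi)
  data.frame(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    group = group,
    age = age, sex = sex, fbg = fbg, glucose_2hpp = g2, tg = tg,
    hba1c = hba1c, activity_hours = act,
    stringsAsFactors = FALSE
  )
}
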