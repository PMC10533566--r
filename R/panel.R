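# The 12-receptor sensing panel.

#' Default 12-receptor sensing panel
#'
#' Describes the twelve sensing spots of the origami sensor: three
#' pyridinoporphyrazines (S1-S3), three pH indicator dyes mixed with
#' tetrabutylammonium hydroxide (S4-S6), three dyes mixed with phenylboronic
#' acid (S7-S9), and three coated silver nanoparticle preparations
#' (S10-S12).  `responsive_to` encodes which study group each receptor
#' reacts to:
#'
#' * both groups: Zn-Pa (S2), MR+TBOH (S5), MB+PBA (S9), TMA-AgNPs (S10)
#' * non-diabetic only: Cu-Pa (S3)
#' * diabetic only: BP+PBA (S7), BR+PBA (S8), CS-AgNPs (S12)
#' * non-responsive to saliva of either group: S1, S4, S6, S11
#'
#' `fbg_link` marks the two receptors whose colour change tracks fasting
#' blood glucose: TMA-AgNPs directly, MR+TBOH through binned FBG categories.
#' `baseline_rgb` is the printed spot colour before sample exposure and
#' `max_delta_rgb` the direction (relative channel weighting) of its colour
#' shift; both are on the 8-bit 0-255 scale.
#'
#' @return A data frame with one row per receptor: `index`, `name`,
#'   `chemistry`, `responsive_to`, `fbg_link`, `baseline_r/g/b`,
#'   `delta_r/g/b`.
#' @export
#' @examples
#' receptor_panel()
receptor_panel <- function() {
  p <- data.frame(
    index = 1:12,
    name = c("Co-Pa", "Zn-Pa", "Cu-Pa", "TB+TBOH", "MR+TBOH", "BB+TBOH",
             "BP+PBA", "BR+PBA", "MB+PBA", "TMA-AgNPs", "Arg-AgNPs",
             "CS-AgNPs"),
    chemistry = c("porphyrazine", "porphyrazine", "porphyrazine",
                  "dye_TBOH", "dye_TBOH", "dye_TBOH",
                  "dye_PBA", "dye_PBA", "dye_PBA",
                  "AgNP", "AgNP", "AgNP"),
    responsive_to = c("none", "both", "nondiabetic", "none", "both", "none",
                      "diabetic", "diabetic", "both", "both", "none",
                      "diabetic"),
    fbg_link = c("none", "none", "none", "none", "binned", "none",
                 "none", "none", "none", "direct", "none", "none"),
    stringsAsFactors = FALSE
  )
  base <- rbind(
    c(20, 60, 50),    # Co-Pa: dark teal
    c(30, 50, 60),    # Zn-Pa
    c(40, 40, 200),   # Cu-Pa: blue
    c(230, 210, 60),  # TB+TBOH: yellow
    c(220, 60, 50),   # MR+TBOH: red
    c(60, 40, 200),   # BB+TBOH: blue-violet
    c(200, 60, 210),  # BP+PBA: purple
    c(220, 40, 40),   # BR+PBA: red
    c(40, 40, 220),   # MB+PBA: blue
    c(230, 200, 50),  # TMA-AgNPs: yellow
    c(235, 210, 60),  # Arg-AgNPs: yellow
    c(240, 220, 60)   # CS-AgNPs: yellow (browns on response)
  )
  dmax <- rbind(
    c(100, 100, 100),
    c(110, 90, 120),
    c(90, 110, 120),
    c(100, 100, 60),
    c(120, 100, 70),
    c(90, 90, 110),
    c(100, 90, 110),
    c(110, 90, 90),
    c(100, 110, 120),
    c(80, 110, 120),
    c(100, 100, 100),
    c(70, 110, 130)
  )
  p$baseline_r <- base[, 1]; p$baseline_g <- base[, 2]; p$baseline_b <- base[, 3]
  p$delta_r <- dmax[, 1]; p$delta_g <- dmax[, 2]; p$delta_b <- dmax[, 3]
  class(p) <- c("receptor_panel", "data.frame")
  p
}

#' Validate a receptor panel
#' @param panel A data frame as returned by [receptor_panel()].
#' @keywords internal
validate_panel <- function(panel) {
  if (nrow(panel) != 12L) {
    stop("receptor panel must describe exactly 12 receptors, got ",
         nrow(panel))
  }
  if (!identical(sort(panel$index), 1:12)) {
    stop("receptor indices must be a permutation of 1..12")
  }
  bad <- !panel$responsive_to %in% c("none", "both", "diabetic", "nondiabetic")
  if (any(bad)) stop("unknown responsive_to value: ", panel$responsive_to[bad][1])
  invisible(panel)
}

# Unit channel-weight vectors (rows; zero row when max_delta is all zero).
panel_weights <- function(panel) {
  w <- as.matrix(panel[, c("delta_r", "delta_g", "delta_b")])
  nrm <- sqrt(rowSums(w^2))
  w[nrm > 0, ] <- w[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  unname(w)
}

# TRUE when receptor `resp` reacts to samples from `group`.
is_responsive <- function(resp, group) {
  resp == "both" | resp == group
}

#' Column names of the 36-feature response matrix (receptor-major order)
#' @param panel Receptor panel; used only for its ordering by `index`.
#' @keywords internal
response_colnames <- function(panel = receptor_panel()) {
  as.vector(t(outer(paste0("S", 1:12), c("R", "G", "B"), paste, sep = "_")))
}
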