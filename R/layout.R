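# Sensor geometry: where the 12 spots sit on the scanned canvas.

#' Define a sensor spot layout
#'
#' Coordinates are pixels, origin at the top-left corner, x rightward,
#' y downward, 0-based.  A pixel belongs to a spot when its centre lies
#' within distance `radius` of the spot centre.  The default is a 3-row x
#' 4-column grid on a 300 x 200 canvas with radius-20 spots, ordered
#' S1..S12 row by row.
#'
#' @param canvas_width,canvas_height Canvas size in pixels.
#' @param spots Data frame with columns `x`, `y`, `r` (one row per spot,
#'   ordered S1..S12), or NULL for the default grid.
#' @return An object of class `sensor_layout`.
#' @export
#' @examples
#' lay <- sensor_layout()
#' lay$spots[1, ]
sensor_layout <- function(canvas_width = 300L, canvas_height = 200L,
                          spots = NULL) {
  if (is.null(spots)) {
    cx <- round((2 * (1:4) - 1) * canvas_width / 8)
    cy <- round((2 * (1:3) - 1) * canvas_height / 6)
    spots <- data.frame(x = rep(cx, times = 3), y = rep(cy, each = 4), r = 20)
  }
  layout <- structure(
    list(canvas_width = as.integer(canvas_width),
         canvas_height = as.integer(canvas_height),
         spots = as.data.frame(spots)),
    class = "sensor_layout")
  validate_layout(layout)
  layout
}

#' Validate a sensor layout
#'
#' Checks spot count, containment in the canvas, and pairwise disjointness.
#' @param layout A `sensor_layout`.
#' @keywords internal
validate_layout <- function(layout) {
  sp <- layout$spots
  if (nrow(sp) != 12L) stop("layout must define exactly 12 spots, got ", nrow(sp))
  if (any(sp$r <= 0)) stop("spot radii must be positive")
  # disk of pixel centres: x in [cx - r, cx + r] must fit in [0, w-1]
  if (any(sp$x - sp$r < 0 | sp$x + sp$r > layout$canvas_width - 1 |
          sp$y - sp$r < 0 | sp$y + sp$r > layout$canvas_height - 1)) {
    stop("layout error: spot disk exceeds the canvas")
  }
  d <- as.matrix(stats::dist(sp[, c("x", "y")]))
  rsum <- outer(sp$r, sp$r, "+")
  diag(d) <- Inf
  if (any(d <= rsum)) stop("layout error: overlapping spots")
  invisible(layout)
}

#' Read / write a layout as YAML
#' @param path File path.
#' @rdname layout_io
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  sensor_layout(y$canvas_width, y$canvas_height,
                data.frame(x = vapply(y$spots, `[[`, 0, "x"),
                           y = vapply(y$spots, `[[`, 0, "y"),
                           r = vapply(y$spots, `[[`, 0, "r")))
}

#' @param layout A `sensor_layout`.
#' @rdname layout_io
#' @export
write_layout <- function(layout, path) {
  yaml::write_yaml(list(
    canvas_width = layout$canvas_width,
    canvas_height = layout$canvas_height,
    spots = lapply(seq_len(nrow(layout$spots)), function(i)
      as.list(layout$spots[i, c("x", "y", "r")]))
  ), path)
  invisible(path)
}

# Logical pixel mask (h x w) of one spot.  X/Y are 0-based pixel centres.
spot_mask <- function(layout, i) {
  sp <- layout$spots[i, ]
  w <- layout$canvas_width; h <- layout$canvas_height
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  (X - sp$x)^2 + (Y - sp$y)^2 <= sp$r^2
}
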