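# Rendering synthetic before/after sensor scans.

#' Render a before/after sensor image pair from a response row
#'
#' Paints each spot with its receptor's baseline colour on a white canvas
#' (the "before" scan), then shifts each spot's colour by the row's
#' per-channel magnitudes (the "after" scan).  The response matrix stores
#' unsigned magnitudes; the shift direction per channel is taken away from
#' the nearer intensity bound (a light baseline darkens, a dark one
#' lightens), flipped if the preferred direction would clip, so that the
#' rendered shift equals the requested magnitude whenever it fits in
#' [0, 255].  Both images are quantised to 8-bit integers.  Optional
#' per-pixel Gaussian noise is seeded from the config's pixel stream.
#'
#' @param response_row Numeric vector of length 36 (channel magnitudes).
#' @param panel Receptor panel, see [receptor_panel()].
#' @param layout A [sensor_layout()].
#' @param config A [generator_config()] (seed for pixel noise).
#' @param pixel_noise_sd Per-pixel Gaussian SD in intensity units
#'   (default 0 = noiseless).
#' @return List with `before` and `after`: h x w x 3 arrays on 0-255.
#' @export
#' @examples
#' cfg <- generator_config(n_diabetic = 1, n_nondiabetic = 1)
#' resp <- generate_responses(generate_cohort(cfg), receptor_panel(), cfg)
#' imgs <- render_sensor_image(resp[1, ], layout = sensor_layout(), config = cfg)
#' dim(imgs$after)
render_sensor_image <- function(response_row, panel = receptor_panel(),
                                layout = sensor_layout(),
                                config = generator_config(),
                                pixel_noise_sd = 0) {
  validate_panel(panel)
  validate_layout(layout)
  response_row <- as.numeric(response_row)
  stopifnot(length(response_row) == 36L)
  panel <- panel[order(panel$index), ]
  h <- layout$canvas_height; w <- layout$canvas_width

  before <- array(255, dim = c(h, w, 3))
  after <- array(255, dim = c(h, w, 3))
  for (s in 1:12) {
    mask <- spot_mask(layout, s)
    base <- c(panel$baseline_r[s], panel$baseline_g[s], panel$baseline_b[s])
    delta <- response_row[(3 * s - 2):(3 * s)]
    shifted <- shift_channels(base, delta)
    for (c in 1:3) {
      ch <- before[, , c]; ch[mask] <- base[c]; before[, , c] <- ch
      ch <- after[, , c]; ch[mask] <- shifted[c]; after[, , c] <- ch
    }
  }
  if (pixel_noise_sd > 0) {
    set.seed(stage_seed(config, "pixels"))
    before <- before + array(stats::rnorm(length(before), 0, pixel_noise_sd),
                             dim = dim(before))
    after <- after + array(stats::rnorm(length(after), 0, pixel_noise_sd),
                           dim = dim(after))
  }
  list(before = quantise8(before), after = quantise8(after))
}

# Apply unsigned channel magnitudes to a baseline colour, shifting away
# from the nearer bound and flipping when the preferred direction clips.
shift_channels <- function(base, delta) {
  out <- numeric(3)
  for (c in 1:3) {
    sgn <- if (base[c] >= 128) -1 else 1
    v <- base[c] + sgn * delta[c]
    if (v < 0 || v > 255) v <- base[c] - sgn * delta[c]
    if (v < 0 || v > 255) {
      warning("channel shift clipped; magnitude ", round(delta[c], 1),
              " does not fit around baseline ", base[c])
      v <- min(max(v, 0), 255)
    }
    out[c] <- v
  }
  out
}

quantise8 <- function(img) {
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

#' Read / write 8-bit RGB PNG sensor images
#'
#' Images are h x w x 3 numeric arrays on the 0-255 scale.
#' @param path PNG file path.
#' @rdname sensor_png
#' @export
read_sensor_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @param image h x w x 3 array, 0-255.
#' @rdname sensor_png
#' @export
write_sensor_png <- function(image, path) {
  png::writePNG(quantise8(image) / 255, path)
  invisible(path)
}
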