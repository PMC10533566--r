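# Feature extraction from before/after sensor scans (the image-analysis
# step of the pipeline: per-spot mean RGB, then 36-element difference
# vectors).

#' Mean RGB intensity per sensing spot
#'
#' Averages each colour channel over the pixels whose (0-based) centres
#' lie within each spot disk (distance <= radius); no partial pixel
#' coverage is modelled.
#'
#' @param image h x w x 3 array on the 0-255 scale.
#' @param layout A [sensor_layout()] matching the image dimensions.
#' @return A 12 x 3 matrix (rows S1..S12, columns R, G, B) of means.
#' @export
extract_spot_means <- function(image, layout) {
  validate_layout(layout)
  check_image(image, layout)
  out <- matrix(NA_real_, 12, 3,
                dimnames = list(paste0("S", 1:12), c("R", "G", "B")))
  for (s in 1:12) {
    mask <- spot_mask(layout, s)
    if (!any(mask)) stop("layout error: spot ", s, " covers zero pixels")
    for (c in 1:3) out[s, c] <- mean(image[, , c][mask])
  }
  out
}

#' Assemble the 36-element response vector from an image pair
#'
#' Element (spot s, channel c) is the absolute difference of spot-mean
#' intensities, `|mean_after - mean_before|`, in receptor-major order
#' (S1_R, S1_G, S1_B, ..., S12_B).
#'
#' @param before_image,after_image h x w x 3 arrays on 0-255 with the
#'   layout's dimensions.
#' @inheritParams extract_spot_means
#' @return Named numeric vector of length 36.
#' @export
compute_response_vector <- function(before_image, after_image, layout) {
  check_same_dim(before_image, after_image)
  mb <- extract_spot_means(before_image, layout)
  ma <- extract_spot_means(after_image, layout)
  v <- as.vector(t(abs(ma - mb)))
  names(v) <- response_colnames()
  v
}

#' Per-pixel absolute difference image ("colour map") for visual QC
#'
#' @inheritParams compute_response_vector
#' @return h x w x 3 array of absolute channel differences, 0-255.
#' @export
make_color_map <- function(before_image, after_image) {
  check_same_dim(before_image, after_image)
  abs(after_image - before_image)
}

check_image <- function(image, layout) {
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L) {
    stop("image error: expected an h x w x 3 RGB array")
  }
  if (d[1] != layout$canvas_height || d[2] != layout$canvas_width) {
    stop("image error: image is ", d[1], "x", d[2], " but layout expects ",
         layout$canvas_height, "x", layout$canvas_width)
  }
  invisible(image)
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("image error: before/after images have mismatched dimensions")
  }
  invisible(NULL)
}
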