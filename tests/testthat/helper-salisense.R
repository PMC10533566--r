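# Shared fixtures, built in code.

small_cfg <- function(seed = 1, nd = 8, nn = 8, ...) {
  generator_config(n_diabetic = nd, n_nondiabetic = nn, seed = seed, ...)
}

# One-spot layout for pixel-level oracles.
one_spot_layout <- function(r = 20, cx = 30, cy = 30, w = 61, h = 61) {
  sp <- data.frame(
    x = c(cx, rep(200, 11) + 45 * (0:10) %% 2 * 0),  # placeholder
    y = c(cy, rep(30, 11)), r = c(r, rep(1, 11)))
  # place the 11 dummy spots on a wide canvas strip so they never overlap
  sp$x[2:12] <- seq(100, 100 + 10 * 45, by = 45)
  sensor_layout(canvas_width = 600, canvas_height = h, spots = sp)
}

# Uniform RGB image for a layout.
uniform_image <- function(layout, rgb = c(0, 0, 0)) {
  h <- layout$canvas_height; w <- layout$canvas_width
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Indices of receptors responsive to a group under the default panel.
is_responsive_set <- function(group) {
  which(salisense:::is_responsive(receptor_panel()$responsive_to, group))
}

default_data <- function(seed = 1) {
  cfg <- generator_config(seed = seed)
  coh <- generate_cohort(cfg)
  list(cfg = cfg, cohort = coh,
       responses = generate_responses(coh, receptor_panel(), cfg))
}
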