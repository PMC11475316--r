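#' Rainbow color mapping for quantitative parameter maps
#'
#' Maps values linearly onto a rainbow hue ramp between `vmin` and `vmax`
#' (values outside the range are clamped to the scale ends). Invalid pixels
#' are rendered in a reserved neutral grey so they are never mistaken for
#' low parameter values.
#'
#' `render_map()` uses the attenuation polarity (low = blue, high = red) with
#' the standard 0-12 1/mm scale; `render_stiffness()` uses the elastography
#' polarity (soft = red, stiff = blue) with the standard 0-600 kPa scale.
#'
#' @param map An `attenuation_map` / `stiffness_map` (or a plain numeric
#'   matrix, in which case every finite pixel is treated as valid).
#' @param vmin,vmax Color scale limits (must satisfy `vmin < vmax`).
#' @param file Optional path; if given the image is also written as PNG.
#' @param invalid_color Length-3 RGB (0-1) used for invalid pixels.
#' @return An `nrow x ncol x 3` RGB array in `[0, 1]`.
#' @export
render_map <- function(map, vmin = 0, vmax = 12, file = NULL,
                       invalid_color = c(0.5, 0.5, 0.5)) {
  render_quant(map, vmin, vmax, polarity = "high_red", file, invalid_color)
}

#' @rdname render_map
#' @export
render_stiffness <- function(map, vmin = 0, vmax = 600, file = NULL,
                             invalid_color = c(0.5, 0.5, 0.5)) {
  render_quant(map, vmin, vmax, polarity = "high_blue", file, invalid_color)
}

render_quant <- function(map, vmin, vmax, polarity = c("high_red", "high_blue"),
                         file = NULL, invalid_color = c(0.5, 0.5, 0.5)) {
  polarity <- match.arg(polarity)
  if (vmin >= vmax) stopf("'vmin' must be < 'vmax' (got %g >= %g)", vmin, vmax)
  if (inherits(map, "param_map")) {
    values <- map$values; valid <- map$valid_mask
  } else if (is.matrix(map)) {
    values <- map; valid <- is.finite(map)
  } else stopf("'map' must be a parameter map or a numeric matrix")
  t <- clamp((values - vmin) / (vmax - vmin), 0, 1)
  t[!valid] <- 0
  # hue ramp between blue (240 deg) and red (0 deg)
  hue <- if (polarity == "high_red") (1 - t) * 4 / 6 else t * 4 / 6
  col <- grDevices::hsv(hue, 1, 1)
  rgb <- grDevices::col2rgb(col) / 255
  img <- array(0, dim = c(nrow(values), ncol(values), 3L))
  for (ch in 1:3) {
    plane <- matrix(rgb[ch, ], nrow(values), ncol(values))
    plane[!valid] <- invalid_color[ch]
    img[, , ch] <- plane
  }
  if (!is.null(file)) png::writePNG(img, file)
  img
}
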