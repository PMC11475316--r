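#' Two-channel OCT intensity stack
#'
#' Container for co- and cross-polarization OCT B-scans acquired from the
#' same tissue area, with the acquisition geometry needed to express depth in
#' millimetres of tissue.
#'
#' @param co,cross Non-negative intensity matrices (depth x lateral), same shape.
#' @param axial_pitch_air Axial pixel pitch in air, mm/px.
#' @param n_tissue Tissue refractive index used to convert air depth to tissue depth.
#' @param lateral_pitch Lateral pixel pitch, mm/px.
#' @param wavelength Central wavelength, um.
#' @param meta Free-form acquisition metadata list.
#' @return A `cpoct_stack` object.
#' @export
cpoct_stack <- function(co, cross, axial_pitch_air, n_tissue = 1.4,
                        lateral_pitch = NA_real_, wavelength = 1.3,
                        meta = list()) {
  if (!is.matrix(co) || !is.matrix(cross)) stopf("'co' and 'cross' must be matrices")
  if (!identical(dim(co), dim(cross))) stopf("'co' and 'cross' must have the same shape")
  if (any(co < 0) || any(cross < 0)) stopf("intensities must be >= 0")
  check_scalar(axial_pitch_air, "axial_pitch_air", 0, strict = TRUE)
  check_scalar(n_tissue, "n_tissue", 1)
  structure(list(co = co, cross = cross, axial_pitch_air = axial_pitch_air,
                 n_tissue = n_tissue, lateral_pitch = lateral_pitch,
                 wavelength = wavelength, meta = meta),
            class = "cpoct_stack")
}

#' @export
print.cpoct_stack <- function(x, ...) {
  cat(sprintf("cpoct_stack: %d x %d px, axial pitch %.4f mm/px (air), n = %.2f\n",
              nrow(x$co), ncol(x$co), x$axial_pitch_air, x$n_tissue))
  invisible(x)
}

#' Phase-sensitive compression series
#'
#' Ordered complex-valued B-scans acquired under increasing uniaxial
#' compression through a calibrated linear reference silicone layer.
#'
#' @param frames Complex array, depth x lateral x frame (>= 2 frames for
#'   strain estimation; a single frame is allowed as a degenerate series).
#' @param axial_pitch_air,n_tissue,wavelength Acquisition geometry as in
#'   [cpoct_stack()].
#' @param reference_region Integer `c(first_row, last_row)` of the silicone layer.
#' @param E_ref Calibrated silicone Young's modulus, kPa.
#' @param tissue_mask Logical matrix (depth x lateral) marking tissue pixels;
#'   must not intersect the reference rows.
#' @param meta Metadata list.
#' @export
compression_series <- function(frames, axial_pitch_air, n_tissue = 1.4,
                               wavelength = 1.3, reference_region, E_ref,
                               tissue_mask = NULL, meta = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L || !is.complex(frames)) {
    stopf("'frames' must be a complex depth x lateral x frame array")
  }
  check_scalar(axial_pitch_air, "axial_pitch_air", 0, strict = TRUE)
  check_scalar(E_ref, "E_ref", 0, strict = TRUE)
  reference_region <- as.integer(reference_region)
  if (length(reference_region) != 2L || reference_region[1] > reference_region[2]) {
    stopf("'reference_region' must be c(first_row, last_row)")
  }
  if (!is.null(tissue_mask)) {
    if (!identical(dim(tissue_mask), dim(frames)[1:2])) {
      stopf("'tissue_mask' shape must match the frames")
    }
    if (reference_region[1] >= 1L &&
        any(tissue_mask[reference_region[1]:reference_region[2], ])) {
      stopf("'tissue_mask' must be disjoint from the reference region")
    }
  }
  structure(list(frames = frames, axial_pitch_air = axial_pitch_air,
                 n_tissue = n_tissue, wavelength = wavelength,
                 reference_region = reference_region, E_ref = E_ref,
                 tissue_mask = tissue_mask, meta = meta),
            class = "compression_series")
}

#' @export
print.compression_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("compression_series: %d x %d px, %d frames, E_ref = %g kPa (rows %d-%d)\n",
              d[1], d[2], d[3], x$E_ref, x$reference_region[1], x$reference_region[2]))
  invisible(x)
}

new_param_map <- function(values, valid_mask, channel, units, params, class) {
  stopifnot(is.matrix(values), identical(dim(values), dim(valid_mask)))
  structure(list(values = values, valid_mask = valid_mask, channel = channel,
                 units = units, params = params),
            class = c(class, "param_map"))
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("%s: %d x %d px (%s), %.1f%% valid, median %.3g %s\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              x$channel %||% "", 100 * mean(x$valid_mask),
              stats::median(x$values[x$valid_mask]), x$units))
  invisible(x)
}

#' @export
summary.param_map <- function(object, ...) {
  v <- object$values[object$valid_mask]
  c(n_valid = length(v), median = stats::median(v),
    q1 = unname(stats::quantile(v, 0.25, type = 7)),
    q3 = unname(stats::quantile(v, 0.75, type = 7)))
}

#' Plot a quantitative parameter map
#'
#' Renders the map on its standard color scale ([render_map()] for
#' attenuation, [render_stiffness()] for stiffness) and draws it as a raster.
#' @param x A map produced by [estimate_attenuation()] or [estimate_stiffness()].
#' @param ... Passed to the renderer (`vmin`, `vmax`, ...).
#' @export
plot.param_map <- function(x, ...) {
  img <- if (inherits(x, "stiffness_map")) render_stiffness(x, ...) else render_map(x, ...)
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = ncol(x$values) / nrow(x$values))
  graphics::rasterImage(img, 0, 0, 1, 1)
  graphics::title(main = sprintf("%s (%s)", class(x)[1], x$units))
  invisible(x)
}
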