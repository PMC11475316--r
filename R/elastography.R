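#' Interframe phasor of a phase-sensitive frame pair
#'
#' Per-pixel product `conj(a) * b`; its argument is the interframe phase
#' difference `delta_phi = 4 * pi * n_tissue * delta_u / lambda`, where
#' `delta_u` is the axial displacement between the two acquisitions.
#'
#' @param frame_a,frame_b Complex matrices of identical shape (earlier and
#'   later frame).
#' @return Complex matrix of the same shape.
#' @export
interframe_phasor <- function(frame_a, frame_b) {
  if (!identical(dim(frame_a), dim(frame_b))) {
    stopf("frames must have identical shape")
  }
  Conj(frame_a) * frame_b
}

#' Vector-method interframe axial strain
#'
#' Estimates the axial gradient of the interframe phase without explicit
#' phase unwrapping. Per pixel, lag-`lag` phasors
#' `c(x, z) = b(x, z + lag) * conj(b(x, z))` are formed from the interframe
#' field `b`, averaged as complex numbers over a `window` (axial x lateral)
#' neighbourhood, and converted to strain
#' \deqn{s = \arg\langle c\rangle \cdot \lambda / (4\pi\, n\, q\, \Delta z),}
#' with `delta_z = axial_pitch_air / n_tissue`. Compressive strain is
#' positive. The per-pixel confidence is the phasor-magnitude ratio
#' `|<c>| / <|c|>` (1 on noiseless data).
#'
#' Pixels whose averaged-phasor argument approaches the `+-pi` wrap limit
#' (`|arg| >= wrap_frac * pi`) are flagged invalid; if more than
#' `max_flagged_frac` of the analyzed pixels are flagged the function stops
#' and advises smaller load steps.
#'
#' @param interframe Complex interframe field ([interframe_phasor()]).
#' @param axial_pitch_air Axial pixel pitch in air, mm/px.
#' @param n_tissue Tissue refractive index.
#' @param wavelength Wavelength, um.
#' @param lag Axial lag `q` in px (>= 1). Larger lags increase phase
#'   sensitivity but lower the wrap limit.
#' @param window Averaging window, `c(axial, lateral)` px.
#' @param wrap_frac Wrap-guard threshold as a fraction of pi.
#' @param max_flagged_frac Maximum tolerated fraction of wrap-flagged pixels
#'   before a hard error.
#' @param mask Optional logical matrix restricting the wrap-fraction census
#'   (e.g. the tissue mask).
#' @return List with matrices `strain` (dimensionless; `NA` in the `lag`
#'   deepest rows and at flagged pixels) and `quality` (in `[0, 1]`).
#' @export
vector_strain <- function(interframe, axial_pitch_air, n_tissue = 1.4,
                          wavelength = 1.3, lag = 4L, window = c(8L, 8L),
                          wrap_frac = 0.95, max_flagged_frac = 0.01,
                          mask = NULL) {
  lag <- as.integer(lag)
  if (lag < 1L) stopf("'lag' must be >= 1 px")
  if (length(window) != 2L || any(window < 1L)) stopf("'window' must be c(wz, wx) >= 1")
  nz <- nrow(interframe); nx <- ncol(interframe)
  if (nz <= lag) stopf("image has fewer depth pixels than the lag")
  dz_um <- axial_pitch_air / n_tissue * 1000

  cpx <- interframe[(lag + 1L):nz, , drop = FALSE] *
    Conj(interframe[1:(nz - lag), , drop = FALSE])
  avg <- boxcar2d(cpx, window[1], window[2])
  mag <- boxcar2d(Mod(cpx), window[1], window[2])
  quality <- ifelse(mag > 0, Mod(avg) / mag, 0)
  ang <- Arg(avg)
  flagged <- abs(ang) >= wrap_frac * pi
  strain <- ang * wavelength / (4 * pi * n_tissue * lag * dz_um)
  strain[flagged] <- NA_real_

  pad <- matrix(NA_real_, lag, nx)
  strain <- rbind(strain, pad)
  quality <- rbind(quality, matrix(0, lag, nx))
  flag_full <- rbind(flagged, matrix(FALSE, lag, nx))

  census <- if (is.null(mask)) matrix(TRUE, nz, nx) else mask
  frac <- mean(flag_full[census & row(flag_full) <= nz - lag])
  if (is.finite(frac) && frac > max_flagged_frac) {
    stopf(paste0("interframe phase exceeds the wrap limit in %.1f%% of analyzed ",
                 "pixels; use smaller load steps"), 100 * frac)
  }
  list(strain = strain, quality = quality, flagged = flag_full)
}

#' Interframe and cumulative strain of a compression series
#'
#' Applies [interframe_phasor()] and [vector_strain()] to every consecutive
#' frame pair of a series and accumulates the interframe strains
#' ([accumulate_strain()]).
#'
#' @param series A [compression_series()].
#' @inheritParams vector_strain
#' @return A `strain_field`: arrays `interframe` and `cumulative`
#'   (depth x lateral x transition) and `quality` (minimum over transitions
#'   up to each frame).
#' @export
estimate_strain_series <- function(series, lag = 4L, window = c(8L, 8L),
                                   wrap_frac = 0.95, max_flagged_frac = 0.01) {
  stopifnot(inherits(series, "compression_series"))
  d <- dim(series$frames)
  if (d[3] < 2L) stopf("need at least 2 frames to estimate strain")
  slices <- vector("list", d[3] - 1L)
  for (k in seq_len(d[3] - 1L)) {
    ifr <- interframe_phasor(series$frames[, , k], series$frames[, , k + 1L])
    slices[[k]] <- vector_strain(ifr, series$axial_pitch_air, series$n_tissue,
                                 series$wavelength, lag = lag, window = window,
                                 wrap_frac = wrap_frac,
                                 max_flagged_frac = max_flagged_frac,
                                 mask = series$tissue_mask)
  }
  accumulate_strain(slices)
}

#' Accumulate interframe strains into cumulative strains
#'
#' Running per-pixel sum of interframe strain slices (small-strain
#' additivity); the per-pixel quality is propagated as the minimum over the
#' transitions accumulated so far.
#'
#' @param slices List of slices as returned by [vector_strain()].
#' @return A `strain_field` object.
#' @export
accumulate_strain <- function(slices) {
  if (!length(slices)) stopf("empty strain series")
  d <- dim(slices[[1]]$strain)
  nk <- length(slices)
  interframe <- array(NA_real_, c(d, nk))
  cumulative <- array(NA_real_, c(d, nk))
  quality <- array(NA_real_, c(d, nk))
  run <- matrix(0, d[1], d[2])
  qmin <- matrix(1, d[1], d[2])
  for (k in seq_len(nk)) {
    s <- slices[[k]]
    if (!identical(dim(s$strain), d)) stopf("inconsistent slice shapes")
    interframe[, , k] <- s$strain
    run <- run + s$strain
    qmin <- pmin(qmin, s$quality)
    cumulative[, , k] <- run
    quality[, , k] <- qmin
  }
  structure(list(interframe = interframe, cumulative = cumulative,
                 quality = quality),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  d <- dim(x$interframe)
  cat(sprintf("strain_field: %d x %d px, %d transitions, final median cumulative strain %.4g\n",
              d[1], d[2], d[3],
              stats::median(x$cumulative[, , d[3]], na.rm = TRUE)))
  invisible(x)
}

#' Applied stress per frame from the reference silicone strain
#'
#' Laterally averages the cumulative strain over the (interior of the)
#' reference silicone rows and converts it with Hooke's law,
#' `sigma = E_ref * eps_ref`. Under the uniaxial-compression contract the
#' stress is depth-uniform in the column, so the same per-frame stress
#' applies to the underlying tissue. Applied stress at the uncompressed first
#' frame is 0.
#'
#' @param strain A `strain_field` from [estimate_strain_series()].
#' @param reference_region `c(first_row, last_row)` of the silicone layer.
#' @param E_ref Calibrated silicone modulus, kPa.
#' @param margin Rows trimmed from each end of the reference region before
#'   averaging (edge transients of the windowed estimator).
#' @return Numeric vector of applied stress (kPa), one per frame including
#'   the zero-stress first frame. Warns if the stress is not monotone under
#'   monotone loading.
#' @export
stress_from_reference <- function(strain, reference_region, E_ref, margin = 8L) {
  stopifnot(inherits(strain, "strain_field"))
  check_scalar(E_ref, "E_ref", 0, strict = TRUE)
  rows <- (reference_region[1] + margin):(reference_region[2] - margin)
  if (!length(rows) || any(rows < 1L)) {
    stopf("reference region too thin for margin = %d", margin)
  }
  nk <- dim(strain$cumulative)[3]
  eps_ref <- vapply(seq_len(nk), function(k) {
    mean(strain$cumulative[rows, , k], na.rm = TRUE)
  }, numeric(1))
  sigma <- c(0, E_ref * eps_ref)
  if (any(diff(sigma) < 0)) {
    warnf("applied stress is not monotone under monotone loading; downstream tangent fits may be unreliable")
  }
  sigma
}

#' Tangent Young's modulus at a prescribed stress level
#'
#' Fits a least-squares line to the stress-strain points whose stress lies
#' within `stress_level +- stress_window` and returns its slope
#' `d sigma / d eps` in kPa. The windowed fit (rather than a two-point
#' finite difference) trades a little locality for noise robustness and
#' reproducibility.
#'
#' @param strain Cumulative strain per frame (dimensionless), same length as
#'   `stress`.
#' @param stress Applied stress per frame, kPa.
#' @param stress_level Stress at which the tangent is evaluated, kPa.
#' @param stress_window Half-width of the fitting window, kPa.
#' @return Tangent modulus, kPa.
#' @examples
#' eps <- seq(0, 0.02, by = 0.002)
#' tangent_modulus(eps, 100 * eps)   # linear tissue: 100 kPa
#' @export
tangent_modulus <- function(strain, stress, stress_level = 1, stress_window = 0.5) {
  if (length(strain) != length(stress)) stopf("strain and stress lengths differ")
  ok <- is.finite(strain) & is.finite(stress)
  strain <- strain[ok]; stress <- stress[ok]
  if (!length(stress) || max(stress) < stress_level + stress_window - 1e-12) {
    stopf("insufficient compression range: curve reaches %.3g kPa, need %.3g kPa",
          if (length(stress)) max(stress) else 0, stress_level + stress_window)
  }
  sel <- abs(stress - stress_level) <= stress_window + 1e-12
  if (sum(sel) < 2L) stopf("fewer than 2 stress-strain points inside the fitting window")
  x <- strain[sel]; y <- stress[sel]
  if (stats::var(x) == 0) stopf("degenerate stress-strain curve (constant strain) in the fitting window")
  unname(stats::cov(x, y) / stats::var(x))
}

#' Per-pixel tangent-stiffness map from a compression series
#'
#' Full compression-elastography chain: interframe vector-method strain,
#' cumulative strain, stress calibration via the reference silicone, and a
#' per-pixel windowed least-squares tangent modulus at `stress_level`.
#'
#' @param series A [compression_series()].
#' @inheritParams vector_strain
#' @inheritParams tangent_modulus
#' @param margin Reference-region trim, see [stress_from_reference()].
#' @param min_quality Pixels whose propagated phasor quality falls below this
#'   value are marked invalid.
#' @return A `stiffness_map` (`values` in kPa, `valid_mask`); the applied
#'   stress per frame and the tissue stress-strain curve (median tissue
#'   strain vs stress) are attached in `$params`.
#' @export
estimate_stiffness <- function(series, lag = 4L, window = c(8L, 8L),
                               stress_level = 1, stress_window = 0.5,
                               wrap_frac = 0.95, max_flagged_frac = 0.01,
                               margin = 8L, min_quality = 0.3) {
  stopifnot(inherits(series, "compression_series"))
  strain <- estimate_strain_series(series, lag = lag, window = window,
                                   wrap_frac = wrap_frac,
                                   max_flagged_frac = max_flagged_frac)
  sigma <- stress_from_reference(strain, series$reference_region,
                                 series$E_ref, margin = margin)
  nk <- dim(strain$cumulative)[3]
  if (max(sigma) < stress_level + stress_window - 1e-12) {
    stopf("insufficient compression range: curve reaches %.3g kPa, need %.3g kPa",
          max(sigma), stress_level + stress_window)
  }
  sel <- which(abs(sigma[-1] - stress_level) <= stress_window + 1e-12)
  if (length(sel) < 2L) stopf("fewer than 2 frames inside the tangent fitting window")
  sig_w <- sigma[-1][sel]
  nz <- dim(strain$cumulative)[1]; nx <- dim(strain$cumulative)[2]
  eps_w <- matrix(0, nz * nx, length(sel))
  for (j in seq_along(sel)) eps_w[, j] <- as.vector(strain$cumulative[, , sel[j]])
  # per-pixel least-squares slope d sigma / d eps over the window frames
  eps_c <- eps_w - rowMeans(eps_w)
  sig_c <- sig_w - mean(sig_w)
  sxx <- rowSums(eps_c^2)
  sxy <- as.vector(eps_c %*% sig_c)
  slope <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  values <- matrix(slope, nz, nx)
  qual <- strain$quality[, , nk]
  valid <- is.finite(values) & values > 0 & qual >= min_quality
  if (!is.null(series$tissue_mask)) valid <- valid & series$tissue_mask
  values[!valid] <- NA_real_
  curve <- data.frame(
    strain = c(0, vapply(seq_len(nk), function(k) {
      stats::median(strain$cumulative[, , k][series$tissue_mask %||% TRUE], na.rm = TRUE)
    }, numeric(1))),
    stress = sigma)
  new_param_map(values, valid, channel = "stiffness", units = "kPa",
                params = list(lag = lag, window = window,
                              stress_level = stress_level,
                              stress_window = stress_window,
                              E_ref = series$E_ref,
                              applied_stress = sigma,
                              stress_strain_curve = curve),
                class = "stiffness_map")
}
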