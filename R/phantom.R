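#' Stress-strain laws for phantom layers
#'
#' Constructors for the constitutive laws a phantom layer can follow under
#' uniaxial compression. The linear law is Hooke's law, `sigma = E * eps`.
#' The exponential law,
#' `sigma(eps) = (E_inf / k) * (exp(k * eps) - 1)`,
#' is a single-parameter-controlled stiffening law whose tangent modulus grows
#' linearly with applied stress, `d sigma / d eps = E_inf + k * sigma`; it
#' mimics the strain-stiffening commonly observed in soft biological tissue.
#'
#' @param E Young's modulus of the linear law, kPa.
#' @param E_inf Zero-stress tangent modulus of the exponential law, kPa.
#' @param k Dimensionless stiffening rate of the exponential law.
#' @return A `stress_strain_law` object.
#' @examples
#' law <- stress_strain_exponential(E_inf = 72, k = 50)
#' law_tangent(law, sigma = 1)  # 72 + 50*1 = 122 kPa
#' @export
stress_strain_linear <- function(E) {
  check_scalar(E, "E", 0, strict = TRUE)
  structure(list(type = "linear", E = E), class = "stress_strain_law")
}

#' @rdname stress_strain_linear
#' @export
stress_strain_exponential <- function(E_inf, k) {
  check_scalar(E_inf, "E_inf", 0, strict = TRUE)
  check_scalar(k, "k", 0, strict = TRUE)
  structure(list(type = "exponential", E_inf = E_inf, k = k),
            class = "stress_strain_law")
}

#' Strain at a given applied stress under a constitutive law
#'
#' For the linear law the inverse is `eps = sigma / E`. For the exponential
#' law the stress-strain relation is inverted numerically (bracketed
#' root-finding on the monotone forward law).
#'
#' @param law A [stress_strain_linear()] or [stress_strain_exponential()] law.
#' @param sigma Applied stress, kPa (scalar or vector, `>= 0`).
#' @return Strain (dimensionless, compressive positive), same length as `sigma`.
#' @export
strain_at_stress <- function(law, sigma) {
  stopifnot(inherits(law, "stress_strain_law"))
  if (any(sigma < 0)) stopf("applied stress must be >= 0")
  if (law$type == "linear") return(sigma / law$E)
  vapply(sigma, function(s) {
    if (s == 0) return(0)
    f <- function(eps) (law$E_inf / law$k) * (exp(law$k * eps) - 1) - s
    hi <- 1e-3
    while (f(hi) < 0) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-14)$root
  }, numeric(1))
}

#' Tangent modulus of a constitutive law at a given stress
#'
#' Closed form: `E` for the linear law, `E_inf + k * sigma` for the
#' exponential law.
#' @inheritParams strain_at_stress
#' @return Tangent modulus `d sigma / d eps` in kPa.
#' @export
law_tangent <- function(law, sigma) {
  stopifnot(inherits(law, "stress_strain_law"))
  if (law$type == "linear") rep_len(law$E, length(sigma)) else law$E_inf + law$k * sigma
}

#' Define one phantom layer
#'
#' @param name Layer label.
#' @param thickness_px Axial thickness in depth pixels.
#' @param mu_co,mu_cross Attenuation coefficients of the layer in the co- and
#'   cross-polarization channels, 1/mm of tissue depth.
#' @param law Stress-strain law of the layer (see [stress_strain_linear()]).
#' @export
phantom_layer <- function(name, thickness_px, mu_co = 0, mu_cross = 0,
                          law = stress_strain_linear(100)) {
  if (!is.character(name) || length(name) != 1L) stopf("layer 'name' must be a string")
  check_scalar(thickness_px, "thickness_px", 0, strict = TRUE)
  check_scalar(mu_co, "mu_co", 0)
  check_scalar(mu_cross, "mu_cross", 0)
  stopifnot(inherits(law, "stress_strain_law"))
  structure(list(name = name, thickness_px = as.integer(thickness_px),
                 mu_co = mu_co, mu_cross = mu_cross, law = law),
            class = "phantom_layer")
}

#' Specify a layered OCT speckle phantom
#'
#' A phantom is an axial stack of homogeneous layers (top to bottom), each
#' with its own attenuation coefficients per polarization channel and a
#' stress-strain law, optionally topped by a linearly elastic reference
#' silicone layer used for stress calibration in compression elastography.
#' Depth pixels below the last layer are treated as signal-free.
#'
#' The default geometry mirrors a common spectral-domain instrument:
#' 256 depth pixels spanning ~1.7 mm in air and 512 lateral pixels spanning
#' 2.4 mm, central wavelength 1.3 um. Depths are converted from air to tissue
#' with the refractive index `n_tissue` (default 1.4, typical soft tissue).
#'
#' @param layers List of [phantom_layer()] objects, ordered top to bottom.
#' @param reference_layer Optional list with `thickness_px`, `E_ref` (kPa,
#'   linear) and optionally `mu` (1/mm, both channels; default 0.3) describing
#'   the calibrated silicone pad placed on top of the layers.
#' @param axial_pitch_air Axial pixel pitch in air, mm/px.
#' @param lateral_pitch Lateral pixel pitch, mm/px.
#' @param n_tissue Tissue group refractive index (>= 1).
#' @param wavelength Central wavelength, um.
#' @param noise_floor Mean intensity of the additive noise floor (0 = none).
#' @param sensitivity Depth sensitivity profile: `"flat"`, or a positive
#'   numeric vector of length `depth_px` (e.g. an exponential roll-off).
#' @param width_px,depth_px Lateral and axial size in pixels.
#' @param seed Integer seed controlling all randomness of the generators.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(layers, reference_layer = NULL,
                         axial_pitch_air = 1.7 / 256, lateral_pitch = 2.4 / 512,
                         n_tissue = 1.4, wavelength = 1.3,
                         noise_floor = 0, sensitivity = "flat",
                         width_px = 512L, depth_px = 256L, seed = 1L) {
  if (inherits(layers, "phantom_layer")) layers <- list(layers)
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "phantom_layer"))) {
    stopf("'layers' must be a list of phantom_layer objects")
  }
  check_scalar(axial_pitch_air, "axial_pitch_air", 0, strict = TRUE)
  check_scalar(lateral_pitch, "lateral_pitch", 0, strict = TRUE)
  check_scalar(n_tissue, "n_tissue", 1)
  check_scalar(wavelength, "wavelength", 0, strict = TRUE)
  check_scalar(noise_floor, "noise_floor", 0)
  check_scalar(width_px, "width_px", 0, strict = TRUE)
  check_scalar(depth_px, "depth_px", 0, strict = TRUE)
  if (!is.null(reference_layer)) {
    check_scalar(reference_layer$thickness_px, "reference_layer$thickness_px", 0, strict = TRUE)
    check_scalar(reference_layer$E_ref, "reference_layer$E_ref", 0, strict = TRUE)
    reference_layer$mu <- reference_layer$mu %||% 0.3
    check_scalar(reference_layer$mu, "reference_layer$mu", 0)
    reference_layer$thickness_px <- as.integer(reference_layer$thickness_px)
  }
  total <- sum(vapply(layers, `[[`, 1L, "thickness_px")) +
    (if (is.null(reference_layer)) 0L else reference_layer$thickness_px)
  if (total > depth_px) {
    stopf("layer thicknesses (%d px incl. reference) exceed depth_px = %d", total, depth_px)
  }
  if (!identical(sensitivity, "flat")) {
    if (!is.numeric(sensitivity) || length(sensitivity) != depth_px || any(sensitivity <= 0)) {
      stopf("'sensitivity' must be \"flat\" or a positive numeric vector of length depth_px")
    }
  }
  structure(list(layers = layers, reference_layer = reference_layer,
                 axial_pitch_air = axial_pitch_air, lateral_pitch = lateral_pitch,
                 n_tissue = n_tissue, wavelength = wavelength,
                 noise_floor = noise_floor, sensitivity = sensitivity,
                 width_px = as.integer(width_px), depth_px = as.integer(depth_px),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("OCT phantom spec: %d x %d px (depth x lateral), pitch %.4f mm/px (air), n = %.2f\n",
              x$depth_px, x$width_px, x$axial_pitch_air, x$n_tissue))
  if (!is.null(x$reference_layer)) {
    cat(sprintf("  reference silicone: %d px, E_ref = %g kPa\n",
                x$reference_layer$thickness_px, x$reference_layer$E_ref))
  }
  for (l in x$layers) {
    cat(sprintf("  layer '%s': %d px, mu_co = %g, mu_cross = %g 1/mm, %s law (tangent@1kPa = %g kPa)\n",
                l$name, l$thickness_px, l$mu_co, l$mu_cross, l$law$type,
                law_tangent(l$law, 1)))
  }
  invisible(x)
}

# per-depth-pixel layer index: 0 = no layer, -1 = reference silicone
layer_index <- function(spec) {
  idx <- integer(spec$depth_px)
  at <- 0L
  if (!is.null(spec$reference_layer)) {
    idx[seq_len(spec$reference_layer$thickness_px)] <- -1L
    at <- spec$reference_layer$thickness_px
  }
  for (i in seq_along(spec$layers)) {
    t <- spec$layers[[i]]$thickness_px
    idx[at + seq_len(t)] <- i
    at <- at + t
  }
  idx
}

mu_profile <- function(spec, channel = c("co", "cross")) {
  channel <- match.arg(channel)
  idx <- layer_index(spec)
  mu <- numeric(spec$depth_px)
  mus <- vapply(spec$layers, `[[`, 0, if (channel == "co") "mu_co" else "mu_cross")
  mu[idx > 0] <- mus[idx[idx > 0]]
  mu[idx == -1L] <- spec$reference_layer$mu
  mu
}

sensitivity_profile <- function(spec) {
  if (identical(spec$sensitivity, "flat")) rep(1, spec$depth_px) else spec$sensitivity
}

#' Generate a two-channel speckled OCT intensity stack with ground truth
#'
#' Builds one B-scan per polarization channel. The ensemble-mean intensity at
#' tissue depth `z` follows a Beer-Lambert decay,
#' `I(z) = s(z) * I0 * exp(-2 * integral(mu))`, with the depth increment per
#' pixel equal to `axial_pitch_air / n_tissue` (mm). Fully developed speckle
#' is modelled as the squared magnitude of a unit-variance circular complex
#' Gaussian field, independent per pixel, and an additive exponential noise
#' floor with mean `noise_floor` is superimposed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `stack` (a `cpoct_stack`: matrices `co` and
#'   `cross` plus acquisition metadata) and `truth` (per-pixel attenuation
#'   maps per channel in 1/mm, a tangent-stiffness-at-1-kPa map in kPa, the
#'   noiseless ensemble-mean profiles and the generator parameters).
#' @examples
#' spec <- phantom_spec(phantom_layer("uniform", 64, mu_co = 2, mu_cross = 1),
#'                      depth_px = 64, width_px = 32, seed = 7)
#' g <- generate_cpoct_stack(spec)
#' dim(g$stack$co)
#' @export
generate_cpoct_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$depth_px; nx <- spec$width_px
  dz <- spec$axial_pitch_air / spec$n_tissue
  sens <- sensitivity_profile(spec)
  truth_mu <- list(co = mu_profile(spec, "co"), cross = mu_profile(spec, "cross"))
  channels <- with_seed(spec$seed, {
    lapply(truth_mu, function(mu) {
      # two-way transmission accumulated over the pixels above
      trans <- exp(-2 * dz * c(0, cumsum(mu)[-nz]))
      mean_i <- sens * trans
      speckle <- matrix(stats::rexp(nz * nx), nz, nx)  # unit-mean, contrast 1
      img <- mean_i * speckle
      if (spec$noise_floor > 0) {
        img <- img + matrix(stats::rexp(nz * nx, rate = 1 / spec$noise_floor), nz, nx)
      }
      list(img = img, mean_profile = mean_i)
    })
  })
  stack <- cpoct_stack(co = channels$co$img, cross = channels$cross$img,
                       axial_pitch_air = spec$axial_pitch_air,
                       n_tissue = spec$n_tissue,
                       lateral_pitch = spec$lateral_pitch,
                       wavelength = spec$wavelength,
                       meta = list(seed = spec$seed, noise_floor = spec$noise_floor))
  truth <- list(
    mu_map_co = matrix(truth_mu$co, nz, nx),
    mu_map_cross = matrix(truth_mu$cross, nz, nx),
    stiffness_map = stiffness_truth_map(spec),
    mean_profile_co = channels$co$mean_profile,
    mean_profile_cross = channels$cross$mean_profile,
    sensitivity = sens, noise_floor = spec$noise_floor, dz_tissue = dz)
  list(stack = stack, truth = truth)
}

stiffness_truth_map <- function(spec, stress_level = 1) {
  idx <- layer_index(spec)
  prof <- rep(NA_real_, spec$depth_px)
  tang <- vapply(spec$layers, function(l) law_tangent(l$law, stress_level), 0)
  prof[idx > 0] <- tang[idx[idx > 0]]
  if (!is.null(spec$reference_layer)) prof[idx == -1L] <- spec$reference_layer$E_ref
  matrix(prof, spec$depth_px, spec$width_px)
}

#' Generate a phase-sensitive compression series with ground truth
#'
#' Simulates complex-valued B-scans acquired under stepwise uniaxial
#' compression through the reference silicone layer. A single complex speckle
#' field (amplitude shaped by the co-channel Beer-Lambert envelope) is
#' phase-modulated frame by frame with
#' `exp(i * 4 * pi * n_tissue * u(x, z) / lambda)`, where `u` is the
#' cumulative axial displacement integrated over the per-layer strains
#' `eps_l(sigma)` prescribed by each layer's stress-strain law (compressive
#' strain positive; the linear reference layer strains as `sigma / E_ref`).
#'
#' The generator enforces the unwrap-free contract of the downstream vector
#' method: for every load step and every layer the interframe phase change
#' across the axial lag `max_lag_px` must stay below pi, otherwise the series
#' is rejected naming the offending layer and step.
#'
#' @param spec A [phantom_spec()] with a `reference_layer`.
#' @param stress_steps Applied stress per frame, kPa; strictly increasing,
#'   starting at 0.
#' @param max_lag_px Axial lag (px) assumed for the phase-wrap safety check.
#' @return A list with `series` (a `compression_series`) and `truth`
#'   (displacement fields in um, per-layer strains per frame, applied stress
#'   per frame and the tangent-stiffness map).
#' @export
generate_compression_series <- function(spec, stress_steps, max_lag_px = 4L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$reference_layer)) {
    stopf("compression series requires a reference_layer in the phantom spec")
  }
  if (length(stress_steps) < 1L || stress_steps[1] != 0 ||
      (length(stress_steps) > 1L && any(diff(stress_steps) <= 0))) {
    stopf("'stress_steps' must start at 0 and be strictly increasing")
  }
  nz <- spec$depth_px; nx <- spec$width_px; nf <- length(stress_steps)
  dz <- spec$axial_pitch_air / spec$n_tissue        # mm/px in tissue
  dz_um <- dz * 1000
  idx <- layer_index(spec)

  laws <- lapply(spec$layers, `[[`, "law")
  names(laws) <- vapply(spec$layers, `[[`, "", "name")
  ref_law <- stress_strain_linear(spec$reference_layer$E_ref)

  # strain per structure (reference + layers) per frame
  eps_ref <- strain_at_stress(ref_law, stress_steps)
  eps_lay <- vapply(laws, strain_at_stress, numeric(nf), sigma = stress_steps)
  if (is.null(dim(eps_lay))) {
    eps_lay <- matrix(eps_lay, nrow = nf, dimnames = list(NULL, names(laws)))
  }

  # phase-wrap guard across the vector-method lag
  wrap_limit <- spec$wavelength / (4 * spec$n_tissue * max_lag_px * dz_um)
  d_eps <- apply(cbind(ref = eps_ref, eps_lay), 2, function(e) diff(c(e[1], e))[-1])
  d_eps <- matrix(d_eps, ncol = 1 + length(laws))
  if (nf > 1L) {
    bad <- which(abs(d_eps) >= wrap_limit, arr.ind = TRUE)
    if (nrow(bad)) {
      b <- bad[1, ]
      nm <- c("reference silicone", names(laws))[b[2]]
      stopf(paste0("phase-wrap risk: step %d -> %d strains layer '%s' by %.4g ",
                   "(limit %.4g for lag %d px); use smaller load steps"),
            b[1], b[1] + 1L, nm, abs(d_eps[b[1], b[2]]), wrap_limit, max_lag_px)
    }
  }

  # per-row strain profile per frame, then cumulative displacement from the top
  eps_rows <- matrix(0, nz, nf)
  for (f in seq_len(nf)) {
    prof <- numeric(nz)
    prof[idx == -1L] <- eps_ref[f]
    sel <- idx > 0
    prof[sel] <- eps_lay[f, idx[sel]]
    eps_rows[, f] <- prof
  }
  u_um <- apply(eps_rows * dz_um, 2, cumsum)        # depth x frame, um

  out <- with_seed(spec$seed + 1L, {
    mu <- mu_profile(spec, "co")
    trans <- exp(-2 * dz * c(0, cumsum(mu)[-nz]))
    amp <- sqrt(sensitivity_profile(spec) * trans)
    base <- matrix(complex(real = stats::rnorm(nz * nx, sd = sqrt(0.5)),
                           imaginary = stats::rnorm(nz * nx, sd = sqrt(0.5))), nz, nx)
    base <- base * amp
    frames <- array(complex(real = 0), dim = c(nz, nx, nf))
    for (f in seq_len(nf)) {
      ph <- exp(1i * 4 * pi * spec$n_tissue * u_um[, f] / spec$wavelength)
      fr <- base * ph
      if (spec$noise_floor > 0) {
        fr <- fr + matrix(complex(real = stats::rnorm(nz * nx, sd = sqrt(spec$noise_floor / 2)),
                                  imaginary = stats::rnorm(nz * nx, sd = sqrt(spec$noise_floor / 2))),
                          nz, nx)
      }
      frames[, , f] <- fr
    }
    frames
  })

  ref_rows <- if (spec$reference_layer$thickness_px > 0) {
    c(1L, spec$reference_layer$thickness_px)
  } else c(0L, 0L)
  series <- compression_series(
    frames = out, axial_pitch_air = spec$axial_pitch_air,
    n_tissue = spec$n_tissue, wavelength = spec$wavelength,
    reference_region = ref_rows, E_ref = spec$reference_layer$E_ref,
    tissue_mask = matrix(idx > 0, nz, nx),
    meta = list(seed = spec$seed, stress_steps = stress_steps))
  truth <- list(
    displacement_fields = array(rep(u_um, each = 1), dim = c(nz, nf),
                                dimnames = NULL),
    layer_strains = cbind(reference = eps_ref, eps_lay),
    applied_stress_per_frame = stress_steps,
    stiffness_map = stiffness_truth_map(spec),
    eps_rows = eps_rows, dz_tissue = dz)
  list(series = series, truth = truth)
}

#' Reference attenuation and stiffness values of endometrial tissue classes
#'
#' Literature-derived medians and quartiles (Me \[Q1; Q3\]) of the co- and
#' cross-polarization attenuation coefficients (1/mm) and of the tangent
#' Young's modulus at 1 kPa (kPa) for nine endometrial tissue classes:
#' normal endometrium (proliferative, secretory, atrophic), endometrial
#' hyperplasia (non-atypical, EIN) and endometrial cancer subtypes
#' (low-grade, high-grade, clear cell, serous). These values parameterize the
#' synthetic phantoms and the class-matched cohort simulator; they are inputs,
#' not outputs, of this package.
#'
#' @param morphology Optional class code (e.g. `"proliferative"`, `"EIN"`,
#'   `"EC_low"`); if given, the single matching row is returned, and an
#'   unknown code is an error.
#' @return A data frame with one row per class: numeric columns
#'   `<modality>_med`, `<modality>_q1`, `<modality>_q3` for modalities
#'   `att_co`, `att_cross`, `stiffness`, plus formatted `Me [Q1; Q3]` strings.
#' @examples
#' endometrial_reference("proliferative")$att_co   # "1.73 [1.50; 1.99]"
#' @export
endometrial_reference <- function(morphology = NULL) {
  ref <- data.frame(
    morphology = c("proliferative", "secretory", "atrophic",
                   "non_atypical", "EIN",
                   "EC_low", "EC_high", "EC_clear", "EC_serous"),
    group = c("normal", "normal", "normal", "hyperplasia", "hyperplasia",
              "EC", "EC", "EC", "EC"),
    att_co_med = c(1.73, 2.43, 2.96, 3.16, 3.14, 5.37, 5.20, 3.25, 5.33),
    att_co_q1 = c(1.50, 2.16, 2.66, 2.69, 2.90, 5.14, 4.88, 2.83, 5.19),
    att_co_q3 = c(1.99, 2.72, 3.26, 3.30, 3.32, 6.07, 5.93, 3.46, 5.61),
    att_cross_med = c(0.61, 1.37, 0.75, 2.15, 2.02, 4.56, 3.88, 2.32, 2.37),
    att_cross_q1 = c(0.47, 1.01, 0.56, 1.62, 1.69, 3.45, 3.06, 1.98, 1.95),
    att_cross_q3 = c(0.76, 1.65, 1.01, 2.53, 2.72, 5.19, 4.70, 2.68, 3.04),
    stiffness_med = c(60, 51, 69, 25, 172, 311, 414, 327, 343),
    stiffness_q1 = c(47, 37, 31, 6, 124, 192, 318, 273, 239),
    stiffness_q3 = c(73, 66, 85, 34, 305, 497, 635, 468, 524),
    stringsAsFactors = FALSE)
  fmt <- function(m, q1, q3, d) sprintf(paste0("%.", d, "f [%.", d, "f; %.", d, "f]"), m, q1, q3)
  ref$att_co <- fmt(ref$att_co_med, ref$att_co_q1, ref$att_co_q3, 2)
  ref$att_cross <- fmt(ref$att_cross_med, ref$att_cross_q1, ref$att_cross_q3, 2)
  ref$stiffness <- fmt(ref$stiffness_med, ref$stiffness_q1, ref$stiffness_q3, 0)
  if (!is.null(morphology)) {
    i <- match(morphology, ref$morphology)
    if (is.na(i)) {
      stopf("unknown morphology '%s'; known: %s", morphology,
            paste(ref$morphology, collapse = ", "))
    }
    return(ref[i, , drop = FALSE])
  }
  ref
}

#' Build a phantom spec matched to a reference tissue class
#'
#' Convenience constructor: a reference silicone pad on top of a homogeneous
#' tissue layer whose attenuation medians and tangent-stiffness-at-1-kPa are
#' taken from [endometrial_reference()]. The tissue follows an exponential
#' stress-strain law with stiffening rate `k` when the class tangent modulus
#' exceeds `k` (so `E_inf = tangent - k > 0`), else a linear law.
#'
#' @param morphology Tissue class code, see [endometrial_reference()].
#' @param k Stiffening rate of the exponential law.
#' @param E_ref Reference silicone modulus, kPa.
#' @param silicone_px Reference layer thickness, px.
#' @param tissue_px Tissue layer thickness, px.
#' @param ... Passed to [phantom_spec()] (geometry, noise, seed, ...).
#' @export
phantom_spec_from_reference <- function(morphology, k = 50, E_ref = 100,
                                        silicone_px = 48L, tissue_px = 200L,
                                        ...) {
  r <- endometrial_reference(morphology)
  tang <- r$stiffness_med
  law <- if (tang > k) stress_strain_exponential(tang - k, k) else stress_strain_linear(tang)
  phantom_spec(
    layers = list(phantom_layer(morphology, tissue_px,
                                mu_co = r$att_co_med, mu_cross = r$att_cross_med,
                                law = law)),
    reference_layer = list(thickness_px = as.integer(silicone_px), E_ref = E_ref),
    ...)
}
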