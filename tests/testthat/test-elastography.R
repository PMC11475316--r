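pitch <- 1.7 / 256
n_tis <- 1.4
lam <- 1.3
dz_um <- pitch / n_tis * 1000

test_that("interframe phasor carries the phase of the later frame", {
  a <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  expect_equal(Arg(interframe_phasor(a, a)), matrix(0, 8, 8))
  b <- a * exp(1i * pi / 4)
  expect_equal(Arg(interframe_phasor(a, b)), matrix(pi / 4, 8, 8))
  expect_error(interframe_phasor(a, a[1:4, ]), "shape")

  # phantom pair with uniform displacement: arg = 4 pi n du / lambda (mod 2 pi)
  spec <- oce_phantom(stress_strain_linear(100), seed = 6)
  g <- generate_compression_series(spec, c(0, 0.2))
  du <- diff(g$truth$displacement_fields[150, ])       # um, tissue row 150
  ifr <- interframe_phasor(g$series$frames[, , 1], g$series$frames[, , 2])
  expected <- (4 * pi * n_tis * du / lam) %% (2 * pi)
  got <- Arg(ifr[150, ]) %% (2 * pi)
  expect_equal(got, rep(expected, ncol(ifr)), tolerance = 1e-10)
})

test_that("vector-method strain is exact on noiseless uniform strain and linear", {
  nz <- 128L; nx <- 32L
  base <- matrix(complex(real = rnorm(nz * nx), imaginary = rnorm(nz * nx)), nz, nx)
  make_pair <- function(s0) {
    u <- (1:nz) * s0 * dz_um
    list(base, base * exp(1i * 4 * pi * n_tis * u / lam))
  }
  s0 <- 1e-3
  fr <- make_pair(s0)
  vs <- vector_strain(interframe_phasor(fr[[1]], fr[[2]]), pitch, n_tis, lam)
  inner <- vs$strain[1:(nz - 4), ]
  expect_lt(max(abs(inner - s0)), 1e-5)
  expect_equal(max(abs(inner - s0)), 0, tolerance = 1e-12)

  # zero displacement -> zero strain
  vz <- vector_strain(interframe_phasor(base, base), pitch, n_tis, lam)
  expect_true(all(vz$strain[1:(nz - 4), ] == 0))

  # doubling every displacement doubles the strain exactly (below wrap)
  fr2 <- make_pair(2 * s0)
  vs2 <- vector_strain(interframe_phasor(fr2[[1]], fr2[[2]]), pitch, n_tis, lam)
  expect_equal(vs2$strain[1:(nz - 4), ], 2 * vs$strain[1:(nz - 4), ],
               tolerance = 1e-12)

  # a strain just beyond the lag-4 wrap limit is flagged and reported
  s_wrap <- lam / (4 * n_tis * 4 * dz_um) * 1.02
  frw <- make_pair(s_wrap)
  expect_error(vector_strain(interframe_phasor(frw[[1]], frw[[2]]),
                             pitch, n_tis, lam), "wrap limit")
})

test_that("quality is 1 on noiseless data and degrades with complex noise", {
  law <- stress_strain_linear(100)
  q_med <- vapply(c(0, 1e-3, 1e-2), function(nf) {
    spec <- oce_phantom(law, seed = 7, noise_floor = nf)
    sf <- estimate_strain_series(generate_compression_series(spec, c(0, 0.3))$series)
    stats::median(sf$quality[60:230, , 1])
  }, numeric(1))
  expect_equal(q_med[1], 1, tolerance = 1e-9)
  expect_true(all(diff(q_med) < 0))
})

test_that("strain accumulation is additive and propagates the worst quality", {
  s1 <- list(strain = matrix(1e-3, 10, 4), quality = matrix(0.9, 10, 4))
  s2 <- list(strain = matrix(1e-3, 10, 4), quality = matrix(0.7, 10, 4))
  s3 <- list(strain = matrix(1e-3, 10, 4), quality = matrix(0.8, 10, 4))
  one <- accumulate_strain(list(s1))
  expect_equal(one$cumulative[, , 1], s1$strain)
  acc <- accumulate_strain(list(s1, s2, s3))
  expect_equal(acc$cumulative[, , 3], matrix(3e-3, 10, 4))
  expect_equal(acc$quality[, , 3], matrix(0.7, 10, 4))
  expect_equal(acc$quality[, , 1], matrix(0.9, 10, 4))

  # phantom multi-step series: cumulative strain tracks the analytic layer strain
  law <- stress_strain_exponential(72, 50)
  spec <- oce_phantom(law, seed = 8)
  g <- generate_compression_series(spec, default_stress_steps)
  sf <- estimate_strain_series(g$series)
  for (k in c(4, 9, 14)) {
    truth_eps <- strain_at_stress(law, default_stress_steps[k + 1])
    got <- stats::median(sf$cumulative[80:220, , k])
    expect_lt(abs(got / truth_eps - 1), 0.02)
  }
})

test_that("reference-layer strain converts to applied stress by Hooke's law", {
  fake <- structure(list(cumulative = array(0.01, c(40, 8, 1)),
                         interframe = array(0.01, c(40, 8, 1)),
                         quality = array(1, c(40, 8, 1))),
                    class = "strain_field")
  expect_equal(stress_from_reference(fake, c(1, 40), E_ref = 100), c(0, 1))
  fake0 <- structure(list(cumulative = array(0, c(40, 8, 1))),
                     class = "strain_field")
  expect_equal(stress_from_reference(fake0, c(1, 40), E_ref = 100), c(0, 0))

  # phantom: prescribed stress schedule is recovered within 2%
  spec <- oce_phantom(stress_strain_linear(150), seed = 9)
  g <- generate_compression_series(spec, default_stress_steps)
  sf <- estimate_strain_series(g$series)
  sigma <- stress_from_reference(sf, g$series$reference_region, g$series$E_ref)
  expect_lt(max(abs(sigma[-1] / default_stress_steps[-1] - 1)), 0.02)

  nonmono <- structure(list(cumulative = array(rep(c(0.01, 0.005), each = 320),
                                               c(40, 8, 2))),
                       class = "strain_field")
  expect_warning(stress_from_reference(nonmono, c(1, 40), 100), "not monotone")
})

test_that("tangent modulus comes from a windowed least-squares slope", {
  eps <- seq(0, 0.02, by = 0.001)
  expect_equal(tangent_modulus(eps, 100 * eps), 100, tolerance = 1e-12)

  # exponential law built to have tangent 122 kPa at 1 kPa applied stress
  law <- stress_strain_exponential(72, 50)
  sigma <- default_stress_steps
  eps <- strain_at_stress(law, sigma)
  got <- tangent_modulus(eps, sigma, stress_level = 1, stress_window = 0.5)
  expect_lt(abs(got / law_tangent(law, 1) - 1), 0.10)
  expect_equal(law_tangent(law, 1), 122)

  expect_error(tangent_modulus(c(0, 0.001), c(0, 0.4)), "insufficient compression range")
})

test_that("recovered stiffness preserves the ordering of the true moduli", {
  meds <- vapply(list(stress_strain_exponential(15, 10),
                      stress_strain_exponential(72, 50),
                      stress_strain_exponential(261, 50)), function(law) {
    spec <- oce_phantom(law, seed = 10, width = 96L, noise_floor = 1e-4)
    sm <- estimate_stiffness(generate_compression_series(spec, default_stress_steps)$series)
    stats::median(sm$values[70:230, ], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_lt(max(abs(meds / c(25, 122, 311) - 1)), 0.10)
})
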