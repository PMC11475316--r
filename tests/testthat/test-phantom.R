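test_that("spec invariants are enforced with informative rejections", {
  expect_error(phantom_spec(phantom_layer("t", 300), depth_px = 256),
               "exceed depth_px")
  expect_error(phantom_layer("t", 10, mu_co = -1), "mu_co")
  expect_error(phantom_layer("t", 0), "thickness_px")
  expect_error(stress_strain_linear(0), "E")
  expect_error(phantom_spec(phantom_layer("t", 10), axial_pitch_air = 0),
               "axial_pitch_air")
  expect_error(phantom_spec(phantom_layer("t", 10), n_tissue = 0.9), "n_tissue")
  expect_error(phantom_spec(phantom_layer("t", 10), sensitivity = c(1, 2)),
               "sensitivity")
})

test_that("ensemble-mean intensity follows the Beer-Lambert closed form", {
  # dz = 0.014/1.4 = 0.01 mm/px, so 100 px = 1 mm of tissue depth
  spec <- phantom_spec(phantom_layer("t", 128, mu_co = 2),
                       axial_pitch_air = 0.014, n_tissue = 1.4,
                       width_px = 20000, depth_px = 128, seed = 11)
  g <- generate_cpoct_stack(spec)
  i10 <- mean(g$stack$co[10, ]); i110 <- mean(g$stack$co[110, ])
  ratio <- i110 / i10
  # speckle is Exp(1): sd of a mean ratio over n A-scans ~ ratio * sqrt(2/n)
  se <- exp(-4) * sqrt(2 / 20000)
  expect_lt(abs(ratio - exp(-4)), 3 * se)

  # no attenuation, no noise, flat sensitivity: constant ensemble mean
  spec0 <- phantom_spec(phantom_layer("t", 64, mu_co = 0),
                        width_px = 20000, depth_px = 64, seed = 12)
  g0 <- generate_cpoct_stack(spec0)
  rm0 <- rowMeans(g0$stack$co)
  expect_lt(max(abs(rm0 - 1)), 4 / sqrt(20000))
  expect_equal(g0$truth$mean_profile_co, rep(1, 64))
})

test_that("speckle is fully developed (unit contrast) and seeds decorrelate", {
  spec <- uniform_phantom(1, width = 20000L, depth = 16L, seed = 3)
  g <- generate_cpoct_stack(spec)
  row <- g$stack$co[8, ]
  expect_lt(abs(stats::sd(row) / mean(row) - 1), 0.05)

  a <- generate_cpoct_stack(uniform_phantom(2, width = 64L, depth = 64L, seed = 1))
  b <- generate_cpoct_stack(uniform_phantom(2, width = 64L, depth = 64L, seed = 1))
  expect_identical(a$stack$co, b$stack$co)
  expect_identical(a$stack$cross, b$stack$cross)
  # decorrelation is a property of the speckle itself, so compare flat
  # (mu = 0) stacks where no common depth trend can induce correlation
  f1 <- generate_cpoct_stack(uniform_phantom(0, width = 64L, depth = 64L, seed = 1))
  f2 <- generate_cpoct_stack(uniform_phantom(0, width = 64L, depth = 64L, seed = 2))
  expect_lt(abs(stats::cor(as.vector(f1$stack$co), as.vector(f2$stack$co))), 0.05)
})

test_that("stress-strain laws invert correctly (closed form and bisection oracle)", {
  expect_equal(strain_at_stress(stress_strain_linear(100), 1), 0.01)
  expect_equal(strain_at_stress(stress_strain_linear(400), 1), 0.0025)
  law <- stress_strain_exponential(E_inf = 100, k = 50)
  got <- strain_at_stress(law, 1)
  expect_equal(got, log(1 + 50 * 1 / 100) / 50, tolerance = 1e-9)
  expect_equal(got, bisect_strain(100, 50, 1), tolerance = 1e-9)
  # tangent closed form: E_inf * exp(k * eps(sigma)) = E_inf + k * sigma
  expect_equal(law_tangent(law, 1), 150)
  expect_equal(100 * exp(50 * got), 150, tolerance = 1e-9)
})

test_that("compression series honours the loading contract and ground truth", {
  law <- stress_strain_linear(100)
  spec <- oce_phantom(law, seed = 4)
  single <- generate_compression_series(spec, 0)
  expect_equal(dim(single$series$frames)[3], 1L)
  expect_true(all(single$truth$displacement_fields == 0))

  g <- generate_compression_series(spec, c(0, 0.5, 1.0))
  # displacement equals the analytic integral of the prescribed layer strains
  dz_um <- spec$axial_pitch_air / spec$n_tissue * 1000
  eps_profile <- function(sigma) {
    c(rep(sigma / 100, 48), rep(strain_at_stress(law, sigma), 200), rep(0, 8))
  }
  for (f in 1:3) {
    u_expected <- cumsum(eps_profile(c(0, 0.5, 1.0)[f]) * dz_um)
    expect_equal(g$truth$displacement_fields[, f], u_expected, tolerance = 1e-12)
  }
  expect_true(all(diff(g$truth$displacement_fields[200, ]) >= 0))

  # two linear layers under 1 kPa strain by sigma/E
  spec2 <- phantom_spec(list(phantom_layer("a", 100, law = stress_strain_linear(100)),
                             phantom_layer("b", 100, law = stress_strain_linear(400))),
                        reference_layer = list(thickness_px = 40, E_ref = 100),
                        width_px = 32, depth_px = 256, seed = 1)
  g2 <- generate_compression_series(spec2, c(0, 1))
  expect_equal(unname(g2$truth$layer_strains[2, c("a", "b")]), c(0.01, 0.0025))

  expect_error(generate_compression_series(spec, c(0.5, 1)), "stress_steps")
  expect_error(generate_compression_series(spec, c(0, 1, 0.5)), "stress_steps")
  # a load step large enough to wrap the lag-4 interframe phase is rejected
  soft <- oce_phantom(stress_strain_linear(20), seed = 4)
  expect_error(generate_compression_series(soft, c(0, 1)), "phase-wrap.*tissue")
})

test_that("reference value table matches the published medians and quartiles", {
  expect_equal(endometrial_reference("proliferative")$att_co, "1.73 [1.50; 1.99]")
  expect_equal(endometrial_reference("EIN")$stiffness, "172 [124; 305]")
  expect_equal(endometrial_reference("EC_high")$stiffness_med, 414)
  expect_equal(nrow(endometrial_reference()), 9L)
  expect_error(endometrial_reference("unknown"), "unknown morphology")
})
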