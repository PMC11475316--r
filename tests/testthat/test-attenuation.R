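pitch <- 1.7 / 256
n_tis <- 1.4
dz <- pitch / n_tis

test_that("estimator equals the geometric-series closed form on noiseless columns", {
  mu <- 3
  img <- matrix(rep(exp(-2 * mu * dz * (0:255)), 16), 256, 16)
  m <- estimate_attenuation(img, axial_pitch_air = pitch, n_tissue = n_tis)
  expected <- (exp(2 * mu * dz) - 1) / (2 * dz)
  expect_gt(sum(m$valid_mask), 2000)
  expect_lt(max(abs(m$values[m$valid_mask] - expected)), 1e-9)
  expect_false(any(m$valid_mask[256, ]))   # deepest pixel never valid

  # two-pixel arithmetic: I = [1, 1], dz = 0.5 mm -> mu_hat[1] = 1
  m2 <- estimate_attenuation(matrix(1, 2, 1), axial_pitch_air = 0.5, n_tissue = 1)
  expect_equal(m2$values[1, 1], 1)
})

test_that("estimator is exactly scale invariant and consistent for small mu*dz", {
  mu <- 2
  img <- matrix(rep(exp(-2 * mu * dz * (0:199)), 8), 200, 8)
  m1 <- estimate_attenuation(img, axial_pitch_air = pitch, n_tissue = n_tis)
  m2 <- estimate_attenuation(img * 731.5, axial_pitch_air = pitch, n_tissue = n_tis)
  expect_equal(m1$values, m2$values, tolerance = 1e-13)
  expect_identical(m1$valid_mask, m2$valid_mask)

  # first-order discretization bias is mu*dz: below 0.5% once mu*dz < 0.005
  img_s <- matrix(rep(exp(-2 * 1 * dz * (0:199)), 8), 200, 8)
  ms <- estimate_attenuation(img_s, axial_pitch_air = pitch, n_tissue = n_tis)
  expect_lt(1 * dz, 0.005)
  expect_lt(abs(stats::median(ms$values[ms$valid_mask]) / 1 - 1), 0.005)
  # and stays below ~2% up to mu*dz = 0.02, shrinking linearly with dz
  expect_lt(abs((exp(2 * 0.02) - 1) / (2 * 0.02) - 1), 0.021)
})

test_that("noise and sensitivity compensation restores the Beer-Lambert mean", {
  rolloff <- exp(-(0:255) / 200)
  spec <- phantom_spec(phantom_layer("t", 256, mu_co = 2.5, mu_cross = 1),
                       width_px = 8000, depth_px = 256,
                       noise_floor = 0.01, sensitivity = rolloff, seed = 21)
  g <- generate_cpoct_stack(spec)
  corrected <- compensate_signal(g$stack, noise_floor = 0.01, sensitivity = rolloff)
  prof <- rowMeans(corrected$co)
  truth <- exp(-2 * 2.5 * dz * (0:255))
  top <- 1:120                        # rows with healthy signal-to-noise
  expect_lt(max(abs(prof[top] / truth[top] - 1)), 0.05)

  # identity configuration is a no-op
  same <- compensate_signal(g$stack, noise_floor = 0, sensitivity = "flat")
  expect_identical(same$co, g$stack$co)

  # exact cancellation collapses the channel and warns
  flat <- cpoct_stack(matrix(5, 32, 8), matrix(10, 32, 8), axial_pitch_air = pitch)
  expect_warning(z <- compensate_signal(flat, noise_floor = 5),
                 "'co' is identically zero")
  expect_true(all(z$co == 0))
  expect_true(all(z$cross == 5))

  # "auto" floor estimates from the deepest 5% and reduces deep bias
  auto <- compensate_signal(g$stack, noise_floor = "auto", sensitivity = rolloff)
  expect_true(all(auto$co >= 0))
  expect_lt(mean(auto$co[250:256, ]), mean(g$stack$co[250:256, ] / rolloff[250:256]))
})

test_that("speckled uniform phantoms are recovered and ordered monotonically", {
  meds <- vapply(c(1, 2, 4, 6), function(mu) {
    g <- generate_cpoct_stack(uniform_phantom(mu, width = 512L, seed = 31))
    m <- estimate_attenuation(g$stack, "co")
    stats::median(m$values[m$valid_mask])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_lt(max(abs(meds / c(1, 2, 4, 6) - 1)), 0.05)
})

test_that("validity guard flags starved tails instead of erroring", {
  img <- matrix(0, 16, 4)
  img[1:4, ] <- 1                      # zero tail below row 4
  m <- estimate_attenuation(img, axial_pitch_air = pitch, n_tissue = n_tis,
                            completion = "none")
  expect_false(any(m$valid_mask[5:16, ]))
  expect_true(all(is.na(m$values[5:16, ])))
})

test_that("maps render with clamping, correct polarity and neutral invalid pixels", {
  vals <- matrix(c(0, 6, 12, 15), 2, 2)
  map <- structure(list(values = vals, valid_mask = matrix(TRUE, 2, 2),
                        channel = "co", units = "1/mm", params = list()),
                   class = c("attenuation_map", "param_map"))
  img <- render_map(map, vmin = 0, vmax = 12)
  expect_equal(img[1, 1, ], c(0, 0, 1))            # vmin -> blue
  expect_equal(img[1, 2, ], c(1, 0, 0))            # vmax -> red
  expect_equal(img[2, 2, ], img[1, 2, ])           # 15 clamps to the 12 color
  expect_error(render_map(map, vmin = 12, vmax = 12), "vmin")

  # stiffness polarity is inverted: stiff = blue, soft = red
  svals <- matrix(c(0, 600, 700, 300), 2, 2)
  smap <- structure(list(values = svals, valid_mask = matrix(TRUE, 2, 2),
                         channel = "stiffness", units = "kPa", params = list()),
                    class = c("stiffness_map", "param_map"))
  simg <- render_stiffness(smap, vmin = 0, vmax = 600)
  expect_equal(simg[1, 1, ], c(1, 0, 0))           # 0 kPa -> red
  expect_equal(simg[2, 1, ], c(0, 0, 1))           # 600 kPa -> blue
  expect_equal(simg[1, 2, ], simg[2, 1, ])         # 700 clamps to blue

  # an all-invalid map renders as the reserved neutral color
  none <- structure(list(values = vals, valid_mask = matrix(FALSE, 2, 2),
                         channel = "co", units = "1/mm", params = list()),
                    class = c("attenuation_map", "param_map"))
  nimg <- render_map(none)
  expect_true(all(nimg == 0.5))
})

test_that("two-layer phantoms recover both layers and the interface row", {
  spec <- phantom_spec(list(phantom_layer("upper", 150, mu_co = 5),
                            phantom_layer("lower", 106, mu_co = 3.5)),
                       width_px = 512, depth_px = 256, seed = 41)
  g <- generate_cpoct_stack(spec)
  m <- estimate_attenuation(g$stack, "co", smooth_lateral = 64, tail_frac = 2e-4)
  l1 <- m$values[1:150, ][m$valid_mask[1:150, ]]
  l2 <- m$values[151:256, ][m$valid_mask[151:256, ]]
  expect_lt(abs(stats::median(l1) / 5 - 1), 0.05)
  expect_lt(abs(stats::median(l2) / 3.5 - 1), 0.05)
  expect_lte(abs(locate_boundary(m) - 151), 3)
})
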