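test_that("region sampling is constant-faithful, deterministic and guarded", {
  vals <- matrix(7.5, 60, 60)
  mask <- matrix(TRUE, 60, 60)
  r <- sample_rois(vals, mask, n_regions = 10, seed = 5)
  expect_equal(r$value, rep(7.5, 10))
  expect_equal(r$n_valid_px, rep(100L, 10))

  r2 <- sample_rois(vals, mask, n_regions = 10, seed = 5)
  expect_identical(r, r2)
  r3 <- sample_rois(vals, mask, n_regions = 10, seed = 6)
  expect_false(identical(r[c("row", "col")], r3[c("row", "col")]))

  # placed regions never overlap and lie fully inside the mask
  for (i in 1:9) for (j in (i + 1):10) {
    expect_true(abs(r$row[i] - r$row[j]) >= 10 || abs(r$col[i] - r$col[j]) >= 10)
  }

  expect_error(sample_rois(matrix(1, 8, 8), matrix(TRUE, 8, 8),
                           region_shape = c(10, 10)),
               "smaller than one")
  # a mask with room for just a few regions reports the feasible count
  small_mask <- matrix(FALSE, 60, 60); small_mask[1:10, 1:25] <- TRUE
  expect_error(sample_rois(vals, small_mask, n_regions = 10),
               "admits only [12] non-overlapping")
})

test_that("region means ignore invalid pixels and pixel ordering", {
  vals <- matrix(rnorm(400), 20, 20)
  valid <- matrix(TRUE, 20, 20); valid[1:5, 1:5] <- FALSE
  mask <- matrix(TRUE, 20, 20)
  r <- sample_rois(vals, mask, n_regions = 2, seed = 3, valid_mask = valid)
  for (i in 1:2) {
    rows <- r$row[i]:(r$row[i] + 9); cols <- r$col[i]:(r$col[i] + 9)
    v <- vals[rows, cols][valid[rows, cols]]
    expect_equal(r$value[i], mean(v))          # equals mean over any ordering
    expect_equal(r$value[i], mean(sample(v)))
  }
})

test_that("descriptives use interpolated quartiles and table formatting", {
  d <- describe_mq(c(1, 2, 3, 4, 5))
  expect_equal(c(d$median, d$q1, d$q3), c(3, 2, 4))
  expect_equal(d$label, "3.00 [2.00; 4.00]")
  d1 <- describe_mq(7)
  expect_equal(c(d1$median, d1$q1, d1$q3), c(7, 7, 7))
  expect_equal(describe_mq(c(1.733, 1.496, 1.988), digits = 2)$label,
               "1.73 [1.61; 1.86]")
  expect_equal(describe_mq(c(124, 172, 305), digits = 0)$label, "172 [148; 238]")
  expect_error(describe_mq(numeric(0)), "empty")
})

test_that("exact Mann-Whitney p equals brute-force enumeration, ties included", {
  got <- mw_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)
  expect_equal(got$method, "exact")

  set.seed(71)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    # small integer pool forces ties in most draws
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(mw_test(x, y)$p, brute_force_mw_p(x, y), tolerance = 1e-12)
    expect_equal(mw_test(x, y)$U, pair_count_u(x, y))
  }

  # tie-free case agrees with the exact Wilcoxon distribution
  for (i in 1:20) {
    x <- sample(seq(1, 999, by = 2), 5)      # odd vs even: never tied
    y <- sample(seq(2, 1000, by = 2), 6)
    expect_equal(mw_test(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample p matches the tie-corrected normal approximation", {
  set.seed(72)
  for (i in 1:20) {
    x <- sample(1:12, 30, replace = TRUE)
    y <- sample(3:14, 25, replace = TRUE)
    got <- mw_test(x, y)
    expect_equal(got$method, "normal")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("pairwise comparison matrix applies a per-modality Bonferroni family", {
  tab <- simulate_reference_cohort(20, classes = c("proliferative", "EIN", "EC_low"),
                                   seed = 13)
  cm <- pairwise_mann_whitney(tab)
  expect_s3_class(cm, "comparison_matrix")
  expect_equal(nrow(cm), 3 * 3)                     # 3 pairs x 3 modalities
  expect_true(all(cm$p_adj >= cm$p - 1e-15))
  expect_true(all(cm$p_adj <= 1))
  expect_equal(cm$p_adj, pmin(1, cm$p * 3))
  expect_true(all(cm$significant == (cm$p_adj < 0.05)))

  # identical groups are never significant
  flat <- data.frame(tissue_class = rep(c("a", "b"), each = 3),
                     modality = "att_co", value = rep(5, 6))
  cmf <- pairwise_mann_whitney(flat)
  expect_equal(cmf$p_adj, 1)

  # a class with a single value is skipped with a warning
  bad <- rbind(tab, data.frame(sample_id = "x", tissue_class = "secretory",
                               modality = "att_co", region_id = 1, value = 2))
  expect_warning(pairwise_mann_whitney(bad), "skipping class")

  # classes drawn from the reference proliferative vs low-grade EC
  # attenuation distributions are flagged significant at n = 100
  tab2 <- simulate_reference_cohort(100, classes = c("proliferative", "EC_low"),
                                    modalities = "att_co", seed = 14)
  cm2 <- pairwise_mann_whitney(tab2)
  expect_true(all(cm2$significant))
})

test_that("null rejection rate of the raw p is near the nominal level", {
  set.seed(73)
  rej <- mean(replicate(300, {
    x <- rnorm(30); y <- rnorm(30)
    mw_test(x, y)$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
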