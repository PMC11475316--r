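#' Two-sided Mann-Whitney U test with exact small-sample enumeration
#'
#' Computes the Mann-Whitney statistic `U` of the first sample (number of
#' (x, y) pairs with `x > y`, counting ties as 1/2) and a two-sided p-value.
#' When both group sizes are at most `exact_max_n` the p-value is exact: the
#' null distribution of `U` is built by full enumeration of all
#' `choose(n1 + n2, n1)` group labelings of the pooled values (ties included),
#' and the two-sided p is the doubled smaller tail, capped at 1. For larger
#' groups the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples (>= 1 value each; >= 2 for a meaningful test).
#' @param exact_max_n Size limit per group for the exact enumeration.
#' @return List with `U` (statistic of `x`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mw_test(c(1, 2, 3), c(4, 5, 6))$p   # exact: 0.1
#' @export
mw_test <- function(x, y, exact_max_n = 8L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stopf("both groups must be non-empty")
  pooled <- c(x, y)
  rk <- rank(pooled)                       # midranks
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max_n && n2 <= exact_max_n) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u_obs, p = 1, method = "normal"))
    mu <- n1 * n2 / 2
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = u_obs, p = p, method = method)
}

#' Pairwise Mann-Whitney comparison matrix with Bonferroni correction
#'
#' For each modality, runs a two-sided Mann-Whitney test ([mw_test()]) on
#' every pair of tissue classes and applies a Bonferroni correction with the
#' family defined as all class pairs within that modality
#' (`p_adj = min(1, p * n_pairs)`). A pair is significant when the adjusted
#' p-value is below `alpha`. Classes with fewer than 2 values are skipped
#' with a warning.
#'
#' @param table Long measurement table with columns `tissue_class`,
#'   `modality`, `value` (see [run_pipeline()] / [simulate_reference_cohort()]).
#' @param alpha Significance level (default 0.05).
#' @param exact_max_n Passed to [mw_test()].
#' @return A `comparison_matrix`: data frame with one row per class pair per
#'   modality (`modality`, `class_a`, `class_b`, `n_a`, `n_b`, `U`, `p`,
#'   `p_adj`, `significant`), with `alpha` as an attribute.
#' @export
pairwise_mann_whitney <- function(table, alpha = 0.05, exact_max_n = 8L) {
  stopifnot(all(c("tissue_class", "modality", "value") %in% names(table)))
  out <- list()
  for (mod in unique(table$modality)) {
    sub <- table[table$modality == mod & is.finite(table$value), ]
    counts <- table(sub$tissue_class)
    small <- names(counts)[counts < 2L]
    if (length(small)) {
      warnf("modality '%s': skipping class(es) with < 2 values: %s",
            mod, paste(small, collapse = ", "))
    }
    classes <- names(counts)[counts >= 2L]
    if (length(classes) < 2L) next
    pairs <- utils::combn(sort(classes), 2)
    m <- ncol(pairs)
    for (j in seq_len(m)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      va <- sub$value[sub$tissue_class == a]
      vb <- sub$value[sub$tissue_class == b]
      tst <- mw_test(va, vb, exact_max_n = exact_max_n)
      out[[length(out) + 1L]] <- data.frame(
        modality = mod, class_a = a, class_b = b,
        n_a = length(va), n_b = length(vb),
        U = tst$U, p = tst$p, p_adj = min(1, tst$p * m),
        method = tst$method, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stopf("no modality had >= 2 classes with >= 2 values")
  res <- do.call(rbind, out)
  res$significant <- res$p_adj < alpha
  structure(res, alpha = alpha, class = c("comparison_matrix", "data.frame"))
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("Pairwise Mann-Whitney comparisons (Bonferroni within modality, alpha = %g)\n",
              attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate a class-labelled measurement cohort from reference quartiles
#'
#' Draws per-region measurement values for each tissue class and modality
#' from a log-normal distribution matched to the reference medians and
#' quartiles ([endometrial_reference()]): `meanlog = log(Me)` and
#' `sdlog = log(Q3 / Q1) / (2 * qnorm(0.75))`. This emulates the pooled
#' region-mean statistics of a measurement campaign without any imaging.
#'
#' @param n_per_class Values drawn per class per modality.
#' @param classes Tissue class codes (default: all reference classes).
#' @param modalities Subset of `c("att_co", "att_cross", "stiffness")`.
#' @param seed Integer seed.
#' @return Long measurement table (`sample_id`, `tissue_class`, `modality`,
#'   `region_id`, `value`).
#' @export
simulate_reference_cohort <- function(n_per_class = 100L,
                                      classes = NULL,
                                      modalities = c("att_co", "att_cross", "stiffness"),
                                      seed = 1L) {
  ref <- endometrial_reference()
  classes <- classes %||% ref$morphology
  if (!all(classes %in% ref$morphology)) {
    stopf("unknown class(es): %s",
          paste(setdiff(classes, ref$morphology), collapse = ", "))
  }
  modalities <- match.arg(modalities, several.ok = TRUE)
  with_seed(seed, {
    rows <- list()
    for (cl in classes) {
      r <- ref[ref$morphology == cl, ]
      for (mod in modalities) {
        med <- r[[paste0(mod, "_med")]]
        q1 <- r[[paste0(mod, "_q1")]]
        q3 <- r[[paste0(mod, "_q3")]]
        sdlog <- log(q3 / q1) / (2 * stats::qnorm(0.75))
        v <- stats::rlnorm(n_per_class, meanlog = log(med), sdlog = sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(cl, "_sim"), tissue_class = cl, modality = mod,
          region_id = seq_len(n_per_class), value = v, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
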