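#' Specify a one-vs-rest diagnostic contrast
#'
#' @param positive,negative Disjoint, non-empty sets of tissue class codes.
#' @param modality One of `"att_co"`, `"att_cross"`, `"stiffness"`.
#' @param direction `"higher"` if larger values indicate the positive
#'   condition, `"lower"` otherwise.
#' @param name Optional label for reports.
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(positive, negative,
                          modality = c("att_co", "att_cross", "stiffness"),
                          direction = c("higher", "lower"), name = NULL) {
  modality <- match.arg(modality)
  direction <- match.arg(direction)
  if (!length(positive) || !length(negative)) {
    stopf("positive and negative class sets must be non-empty")
  }
  if (length(intersect(positive, negative))) {
    stopf("positive and negative class sets overlap: %s",
          paste(intersect(positive, negative), collapse = ", "))
  }
  structure(list(positive = positive, negative = negative,
                 modality = modality, direction = direction,
                 name = name %||% paste0(modality, "_contrast")),
            class = "contrast_spec")
}

#' ROC curve by threshold sweep
#'
#' Sweeps every distinct observed value as a candidate threshold (a value
#' equal to the threshold is called positive: `>=` under
#' `direction = "higher"`, `<=` under `"lower"`) and records the true- and
#' false-positive rate at each point. The AUC is the trapezoidal area of the
#' sweep, which equals the pairwise-comparison probability
#' `P(pos > neg) + 0.5 * P(pos = neg)` (the rescaled Mann-Whitney statistic).
#'
#' @param pos,neg Numeric measurement values of the positive and negative
#'   groups (>= 1 each).
#' @param direction See [contrast_spec()].
#' @return A `roc_result`: data frame `points` (`threshold`, `tpr`, `fpr`,
#'   ordered by increasing FPR/TPR from the strictest threshold), `auc`, and
#'   the input summary. No operating threshold is chosen yet (see
#'   [select_threshold()]).
#' @examples
#' roc_curve(c(3, 5), c(1, 4))$auc   # 0.75
#' @export
roc_curve <- function(pos, neg, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (!length(pos) || !length(neg)) {
    stopf("both the positive and negative side must contain at least one value")
  }
  s <- if (direction == "higher") 1 else -1
  thr <- sort(unique(c(pos, neg)), decreasing = (direction == "higher"))
  tpr <- vapply(thr, function(t) mean(s * pos >= s * t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s * neg >= s * t), numeric(1))
  points <- data.frame(threshold = c(if (direction == "higher") Inf else -Inf, thr),
                       tpr = c(0, tpr), fpr = c(0, fpr))
  # trapezoid over the sweep (FPR is nondecreasing along the sweep)
  auc <- sum(diff(c(points$fpr, 1)) * (c(points$tpr, 1) [-1] + points$tpr) / 2)
  structure(list(points = points, auc = auc, direction = direction,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d positive vs %d negative (%s is positive), AUC = %.3f\n",
              x$n_pos, x$n_neg, x$direction, x$auc))
  if (!is.null(x$chosen)) {
    cat(sprintf("  threshold %.4g (%s): Se = %.1f%%, Sp = %.1f%%\n",
                x$chosen$threshold, x$chosen$policy, x$chosen$se, x$chosen$sp))
  }
  invisible(x)
}

#' Plot an ROC curve
#' @param x A `roc_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  if (!is.null(x$chosen)) {
    graphics::points(1 - x$chosen$sp / 100, x$chosen$se / 100, pch = 17)
  }
  invisible(x)
}

#' Select an operating threshold on an ROC curve
#'
#' Policies: `"youden"` maximizes `TPR - FPR`; `"closest01"` minimizes the
#' Euclidean distance to the perfect-classifier corner (0, 1). Ties are
#' broken toward higher specificity (lower FPR). Sensitivity and specificity
#' at the chosen point are returned in percent.
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @param policy `"youden"` or `"closest01"`.
#' @return The `roc_result` with a `chosen` component
#'   (`threshold`, `se`, `sp`, `policy`).
#' @export
select_threshold <- function(roc, policy = "youden") {
  stopifnot(inherits(roc, "roc_result"))
  if (!is.character(policy) || length(policy) != 1L ||
      !policy %in% c("youden", "closest01")) {
    stopf("unknown threshold policy '%s'; available: youden, closest01",
          as.character(policy)[1])
  }
  p <- roc$points[is.finite(roc$points$threshold), ]
  score <- switch(policy,
                  youden = p$tpr - p$fpr,
                  closest01 = -sqrt((1 - p$tpr)^2 + p$fpr^2))
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[which.min(p$fpr[best])]
  roc$chosen <- list(threshold = p$threshold[best],
                     se = 100 * p$tpr[best], sp = 100 * (1 - p$fpr[best]),
                     policy = policy)
  roc
}

#' Classify values by a diagnostic threshold
#'
#' The boundary value counts as positive: `value >= threshold` under
#' `direction = "higher"`, `value <= threshold` under `"lower"`.
#'
#' @param values Numeric vector (may be empty).
#' @param threshold Decision threshold in modality units.
#' @param direction See [contrast_spec()].
#' @return Logical vector, `TRUE` = positive call.
#' @export
classify <- function(values, threshold, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (!length(values)) return(logical(0))
  if (direction == "higher") values >= threshold else values <= threshold
}

#' ROC analysis of a measurement table under a contrast
#'
#' Extracts the positive- and negative-class values of the contrast's
#' modality from a long measurement table, builds the ROC curve and selects
#' an operating threshold.
#'
#' @param table Long measurement table (`tissue_class`, `modality`, `value`).
#' @param contrast A [contrast_spec()].
#' @param policy Threshold policy, see [select_threshold()].
#' @return A `roc_result` with the chosen threshold and the contrast attached.
#' @export
roc_analysis <- function(table, contrast, policy = "youden") {
  stopifnot(inherits(contrast, "contrast_spec"))
  sub <- table[table$modality == contrast$modality & is.finite(table$value), ]
  pos <- sub$value[sub$tissue_class %in% contrast$positive]
  neg <- sub$value[sub$tissue_class %in% contrast$negative]
  roc <- roc_curve(pos, neg, direction = contrast$direction)
  roc <- select_threshold(roc, policy = policy)
  roc$contrast <- contrast
  roc
}

#' Standard diagnostic contrasts for endometrial tissue classes
#'
#' Two clinically motivated one-vs-rest contrasts: endometrial cancer (all
#' subtypes) versus non-tumorous tissue (normal endometrium and hyperplasia,
#' EIN included among the negatives), and EIN versus benign tissue (normal
#' endometrium and non-atypical hyperplasia). All three modalities use
#' higher-is-positive: attenuation and stiffness increase toward malignancy.
#'
#' @param modality Modality for which to build the contrasts.
#' @param include_ein_negative Whether EIN counts as negative in the
#'   EC-vs-non-tumorous contrast (default `TRUE`).
#' @return Named list of two [contrast_spec()]s: `ec_vs_nontumor`,
#'   `ein_vs_benign`.
#' @export
standard_contrasts <- function(modality = c("att_co", "att_cross", "stiffness"),
                               include_ein_negative = TRUE) {
  modality <- match.arg(modality)
  ec <- c("EC_low", "EC_high", "EC_clear", "EC_serous")
  benign <- c("proliferative", "secretory", "atrophic", "non_atypical")
  neg_ec <- if (include_ein_negative) c(benign, "EIN") else benign
  list(
    ec_vs_nontumor = contrast_spec(ec, neg_ec, modality, "higher",
                                   name = paste0("EC_vs_nontumor_", modality)),
    ein_vs_benign = contrast_spec("EIN", benign, modality, "higher",
                                  name = paste0("EIN_vs_benign_", modality)))
}
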