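#' Sample non-overlapping measurement regions inside a mask
#'
#' Draws `n_regions` uniformly random, non-overlapping, axis-aligned
#' rectangular regions that lie fully inside `mask`, and returns the mean map
#' value of each region (computed over the pixels that are also valid in
#' `valid_mask`). Placement is deterministic for a fixed `seed`. Regions are
#' non-overlapping so that no pixel is double-counted in pooled statistics.
#'
#' @param map A parameter map (from [estimate_attenuation()] /
#'   [estimate_stiffness()]) or a numeric matrix.
#' @param mask Logical matrix: where regions may be placed (e.g. the tissue
#'   layer projection).
#' @param n_regions Number of regions (default 10).
#' @param region_shape `c(rows, cols)` in px (default 10 x 10).
#' @param seed Integer seed for the placement.
#' @param valid_mask Optional logical matrix overriding the map's validity.
#' @param max_tries Rejection-sampling budget.
#' @return Data frame with `region_id`, `row`, `col` (top-left corner),
#'   `value` (region mean) and `n_valid_px`. Errors if the mask cannot host
#'   `n_regions` non-overlapping regions, reporting the feasible count.
#' @export
sample_rois <- function(map, mask, n_regions = 10L, region_shape = c(10L, 10L),
                        seed = 1L, valid_mask = NULL, max_tries = 5000L) {
  if (inherits(map, "param_map")) {
    values <- map$values
    valid_mask <- valid_mask %||% map$valid_mask
  } else {
    values <- map
    valid_mask <- valid_mask %||% is.finite(values)
  }
  stopifnot(is.matrix(values), identical(dim(values), dim(mask)))
  rh <- as.integer(region_shape[1]); rw <- as.integer(region_shape[2])
  nz <- nrow(mask); nx <- ncol(mask)
  if (rh > nz || rw > nx) {
    stopf("mask (%d x %d) is smaller than one %d x %d region", nz, nx, rh, rw)
  }
  # top-left corners whose full region lies inside the mask (summed-area table)
  sat <- matrix(0, nz + 1L, nx + 1L)
  sat[-1L, -1L] <- t(apply(apply(mask * 1, 2, cumsum), 1, cumsum))
  ri <- seq_len(nz - rh + 1L); ci <- seq_len(nx - rw + 1L)
  cnt <- sat[ri + rh, ci + rw, drop = FALSE] - sat[ri, ci + rw, drop = FALSE] -
    sat[ri + rh, ci, drop = FALSE] + sat[ri, ci, drop = FALSE]
  cand <- which(cnt == rh * rw, arr.ind = TRUE)
  if (nrow(cand) < 1L) {
    stopf("mask admits 0 placements of a %d x %d region (requested %d)", rh, rw, n_regions)
  }
  chosen <- with_seed(seed, {
    ord <- sample.int(nrow(cand))
    picked <- matrix(0L, 0, 2)
    for (i in ord) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (nrow(picked)) {
        overlap <- any(abs(picked[, 1] - r) < rh & abs(picked[, 2] - c) < rw)
        if (overlap) next
      }
      picked <- rbind(picked, c(r, c))
      if (nrow(picked) == n_regions) break
    }
    picked
  })
  if (nrow(chosen) < n_regions) {
    stopf("mask admits only %d non-overlapping %d x %d regions (requested %d)",
          nrow(chosen), rh, rw, n_regions)
  }
  res <- data.frame(region_id = seq_len(n_regions), row = chosen[, 1],
                    col = chosen[, 2], value = NA_real_, n_valid_px = 0L)
  for (i in seq_len(n_regions)) {
    rr <- chosen[i, 1]:(chosen[i, 1] + rh - 1L)
    cc <- chosen[i, 2]:(chosen[i, 2] + rw - 1L)
    v <- values[rr, cc][valid_mask[rr, cc]]
    res$n_valid_px[i] <- length(v)
    res$value[i] <- if (length(v)) mean(v) else NA_real_
  }
  res
}

#' Median and quartile descriptives in "Me [Q1; Q3]" form
#'
#' Median and 25th/75th percentiles with the linear-interpolation quartile
#' convention (R quantile type 7), formatted the way quantitative OCT tables
#' report them: 2 decimals for attenuation (1/mm), integers for stiffness
#' (kPa).
#'
#' @param values Numeric vector (>= 1 finite value).
#' @param digits Decimals in the formatted string (2 for 1/mm, 0 for kPa).
#' @return List with `median`, `q1`, `q3` and the formatted `label`.
#' @examples
#' describe_mq(c(1, 2, 3, 4, 5))$label   # "3.00 [2.00; 4.00]"
#' @export
describe_mq <- function(values, digits = 2) {
  values <- values[is.finite(values)]
  if (!length(values)) stopf("empty input: descriptives need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  label <- sprintf(paste0("%.", digits, "f [%.", digits, "f; %.", digits, "f]"),
                   q[2], q[1], q[3])
  list(median = q[2], q1 = q[1], q3 = q[3], label = label)
}

#' Assemble a measurement table row block
#'
#' Helper used by the pipeline: turns the region means of one map into rows
#' of the long measurement table (`sample_id`, `tissue_class`, `modality`,
#' `region_id`, `value`, `row`, `col`).
#' @noRd
measurement_rows <- function(rois, sample_id, tissue_class, modality) {
  data.frame(sample_id = sample_id, tissue_class = tissue_class,
             modality = modality, region_id = rois$region_id,
             value = rois$value, row = rois$row, col = rois$col,
             stringsAsFactors = FALSE)
}
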