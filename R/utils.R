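#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators do not
#' leak randomness into (or out of) the caller's session.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Edge-renormalized boxcar mean along rows or columns of a matrix
#'
#' Window means are computed over the window truncated at the matrix edges and
#' divided by the number of contributing samples, so a constant input is
#' reproduced exactly everywhere (including the borders). Works for numeric
#' and complex matrices.
#' @noRd
boxcar1d <- function(m, w, along = c("lateral", "axial")) {
  along <- match.arg(along)
  if (w <= 1) return(m)
  if (along == "axial") return(t(boxcar1d(t(m), w, "lateral")))
  n <- ncol(m)
  h1 <- (w - 1L) %/% 2L
  h2 <- w - 1L - h1
  # cumulative sums along each row, padded with a zero column
  cs <- m
  for (j in seq_len(n)[-1]) cs[, j] <- cs[, j] + cs[, j - 1L]
  cs <- cbind(0, cs)
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  out <- cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
  cnt <- matrix(hi - lo + 1L, nrow = nrow(m), ncol = n, byrow = TRUE)
  out / cnt
}

#' Separable 2D boxcar mean (axial x lateral window), edge-renormalized
#' @noRd
boxcar2d <- function(m, wz, wx) {
  boxcar1d(boxcar1d(m, wz, "axial"), wx, "lateral")
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a finite numeric scalar", name)
  }
  if (strict && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict && x < lower) stopf("'%s' must be >= %g", name, lower)
  invisible(x)
}
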