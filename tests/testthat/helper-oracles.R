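# Independent oracles and small fixture builders shared across the suite.

# Mann-Whitney U by direct pair counting (ties count 1/2)
pair_count_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of all group
# labelings of the pooled values, with the doubled-smaller-tail rule.
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- pair_count_u(x, y)
  cmb <- utils::combn(length(pooled), n1)
  us <- apply(cmb, 2, function(ix) pair_count_u(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# AUC by the pairwise-comparison probability P(pos > neg) + 0.5 P(pos = neg)
pairwise_auc <- function(pos, neg, direction = "higher") {
  if (direction == "lower") {
    pos <- -pos; neg <- -neg
  }
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Strain of the exponential stress-strain law by bisection on the forward law
bisect_strain <- function(E_inf, k, sigma, tol = 1e-12) {
  f <- function(eps) (E_inf / k) * (exp(k * eps) - 1) - sigma
  lo <- 0; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Uniform single-layer phantom spec used by several tests
uniform_phantom <- function(mu, width = 256L, depth = 256L, seed = 1L, ...) {
  phantom_spec(phantom_layer("uniform", depth, mu_co = mu, mu_cross = mu / 2),
               width_px = width, depth_px = depth, seed = seed, ...)
}

# Compression phantom: silicone pad over one tissue layer
oce_phantom <- function(law, E_ref = 100, seed = 1L, width = 128L,
                        noise_floor = 0, mu = 1.5) {
  phantom_spec(phantom_layer("tissue", 200L, mu_co = mu, law = law),
               reference_layer = list(thickness_px = 48L, E_ref = E_ref),
               width_px = width, depth_px = 256L,
               noise_floor = noise_floor, seed = seed)
}

# Stress schedule whose per-step strain stays below the lag-4 wrap limit for
# tangent-at-1kPa moduli down to ~15 kPa
default_stress_steps <- seq(0, 1.68, by = 0.12)
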