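# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: dense matrix powers instead of the negative-binomial
# CDF, grid scans instead of Brent root finding.

# failure probability by iterated dense vector-matrix products
dense_power_failure_prob <- function(chain, x) {
  P <- transition_matrix(chain)
  v <- if (is.null(chain$p0)) {
    c(1, rep(0, chain$b_levels - 1))
  } else {
    chain$p0
  }
  out <- numeric(length(x))
  xs <- sort(unique(x))
  step <- 0
  for (i in seq_along(xs)) {
    while (step < xs[i]) {
      v <- as.vector(v %*% P)
      step <- step + 1
    }
    out[x == xs[i]] <- v[chain$b_levels]
  }
  out
}

# Neuber root by dense-grid sign change + bisection on the raw residual
neuber_bisect_oracle <- function(sigma_el, E, k, n_prime, iters = 200) {
  eps_el <- sigma_el / E
  f <- function(s) s / E + (s / k)^(1 / n_prime) - eps_el^2 * E / s
  lo <- sigma_el * 1e-6
  hi <- sigma_el * (1 + 1e-12)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Coffin-Basquin-Manson inversion by scanning a dense log grid of reversals
cm_grid_oracle <- function(delta_eps_ep, E, props, n_grid = 1e6,
                           log_range = c(0, 12)) {
  l <- seq(log_range[1], log_range[2], length.out = n_grid)
  rhs <- (props$sigma_f_prime / E) * 10^(l * props$b_exp) +
    props$epsilon_f_prime * 10^(l * props$c_exp)
  amp <- delta_eps_ep / 2
  i <- which(rhs <= amp)[1]  # rhs is decreasing
  # linear interpolation in log space between the bracketing grid points
  w <- (rhs[i - 1] - amp) / (rhs[i - 1] - rhs[i])
  10^(l[i - 1] + w * (l[i] - l[i - 1])) / 2
}

# total area of a region of a mesh
region_area <- function(mesh, region) {
  idx <- which(mesh$region == region)
  x1 <- mesh$nodes[mesh$elements[idx, 1], 1]
  y1 <- mesh$nodes[mesh$elements[idx, 1], 2]
  x2 <- mesh$nodes[mesh$elements[idx, 2], 1]
  y2 <- mesh$nodes[mesh$elements[idx, 2], 2]
  x3 <- mesh$nodes[mesh$elements[idx, 3], 1]
  y3 <- mesh$nodes[mesh$elements[idx, 3], 2]
  sum(((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2)
}

# element centroids
element_centroids <- function(mesh) {
  cbind((mesh$nodes[mesh$elements[, 1], 1] +
           mesh$nodes[mesh$elements[, 2], 1] +
           mesh$nodes[mesh$elements[, 3], 1]) / 3,
        (mesh$nodes[mesh$elements[, 1], 2] +
           mesh$nodes[mesh$elements[, 2], 2] +
           mesh$nodes[mesh$elements[, 3], 2]) / 3)
}
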