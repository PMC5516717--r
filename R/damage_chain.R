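#' Construct a unit-jump Markov cumulative damage chain
#'
#' The Bogdanoff-Kozin "B-model" discretises the life of a component into
#' `b_levels` damage levels, the last of which (level `b`) is absorbing
#' failure. Each duty (damage) cycle the component either stays at its current
#' level, with probability `p_j`, or jumps to the next level, with probability
#' `q_j = 1 - p_j`. The chain is parameterised by the stay/jump ratio
#' `r_j = p_j / q_j`; under the constant-severity hypothesis a single scalar
#' `r` characterises every transient level and the cycles-to-failure variable
#' becomes a shifted negative binomial.
#'
#' @param b_levels Integer number of damage levels (>= 2); failure occurs at
#'   level `b_levels`.
#' @param r Stay/jump ratio(s) `p/q`, non-negative. Either a single scalar
#'   (uniform, constant-severity chain) or a vector of length `b_levels - 1`
#'   giving one ratio per transient level.
#' @param p0 Initial distribution over the `b_levels` levels. Defaults to
#'   `NULL`, meaning a point mass at level 1 (a pristine component) — stored
#'   symbolically so chains with billions of levels stay cheap. When given
#'   explicitly it must sum to 1 with zero mass on the failure level.
#' @return An object of class `damage_chain`.
#' @examples
#' ch <- damage_chain(b_levels = 4, r = 1)
#' transition_matrix(ch)
#' chain_moments(ch)
#' @export
damage_chain <- function(b_levels, r, p0 = NULL) {
  # kept as a whole-valued double: level counts from megacycle-scale lives
  # exceed the 32-bit integer range
  if (length(b_levels) != 1L || !is.finite(b_levels) || b_levels < 2 ||
      b_levels != round(b_levels)) {
    stop("`b_levels` must be a single whole number >= 2", call. = FALSE)
  }
  b_levels <- round(b_levels)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0)) {
    stop("`r` must be finite and >= 0", call. = FALSE)
  }
  uniform <- length(r) == 1L
  if (!uniform && length(r) != b_levels - 1L) {
    stop("`r` must be a scalar or have length b_levels - 1", call. = FALSE)
  }
  if (!is.null(p0)) {
    if (length(p0) != b_levels) {
      stop("`p0` must have length b_levels", call. = FALSE)
    }
    if (any(p0 < 0) || abs(sum(p0[-b_levels]) - 1) > 1e-12 ||
        p0[b_levels] != 0) {
      stop("`p0` must be a distribution over levels 1..b-1 with p0[b] = 0",
           call. = FALSE)
    }
  }
  structure(
    list(b_levels = b_levels, r = r, uniform_r = uniform, p0 = p0),
    class = "damage_chain"
  )
}

#' @export
print.damage_chain <- function(x, ...) {
  cat("Bogdanoff-Kozin damage chain\n")
  cat("  damage levels (b):", x$b_levels, "\n")
  if (x$uniform_r) {
    cat("  stay/jump ratio r:", format(x$r), "(uniform)\n")
  } else {
    cat("  stay/jump ratio r: per-level, range",
        format(min(x$r)), "-", format(max(x$r)), "\n")
  }
  if (pristine_start(x)) {
    cat("  initial state: pristine (level 1)\n")
  } else {
    cat("  initial state: distributed over levels\n")
  }
  invisible(x)
}

pristine_start <- function(chain) {
  is.null(chain$p0) || chain$p0[1] == 1
}

# explicit initial-distribution vector (materialises the default point mass)
p0_vector <- function(chain) {
  if (is.null(chain$p0)) c(1, rep(0, chain$b_levels - 1)) else chain$p0
}

# per-level ratio vector, length b - 1; only for operations that walk the
# levels explicitly, so guard against absurd materialisations
r_levels <- function(chain) {
  if (chain$b_levels > 1e7) {
    stop("per-level operations are not supported for chains with more than ",
         "1e7 levels; use the closed forms", call. = FALSE)
  }
  if (chain$uniform_r) rep(chain$r, chain$b_levels - 1) else chain$r
}

#' Probability transition matrix of a damage chain
#'
#' Builds the dense `b x b` upper-bidiagonal transition matrix: diagonal
#' entries are the stay probabilities `p_j = r_j / (1 + r_j)`, the
#' superdiagonal holds the jump probabilities `q_j = 1 - p_j`, and the last
#' row is the absorbing failure state. Intended for inspection and for small
#' chains; state evolution for large chains uses the sparse recurrence in
#' [damage_state_distribution()].
#'
#' @param chain A [damage_chain()].
#' @return A `b_levels` x `b_levels` row-stochastic matrix.
#' @export
transition_matrix <- function(chain) {
  stopifnot(inherits(chain, "damage_chain"))
  b <- chain$b_levels
  r <- r_levels(chain)
  p <- r / (1 + r)
  P <- matrix(0, b, b)
  for (j in seq_len(b - 1L)) {
    P[j, j] <- p[j]
    P[j, j + 1L] <- 1 - p[j]
  }
  P[b, b] <- 1
  P
}

#' Damage-state distribution after x duty cycles
#'
#' Evolves the initial distribution through `x` steps of the chain,
#' `p_x = p_0 P^x`, using the bidiagonal recurrence (one vector pass per
#' step) rather than dense matrix powers.
#'
#' @param chain A [damage_chain()].
#' @param x Non-negative integer number of duty cycles.
#' @return Numeric vector of length `b_levels` summing to 1.
#' @export
damage_state_distribution <- function(chain, x) {
  stopifnot(inherits(chain, "damage_chain"))
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 0L) {
    stop("`x` must be a single non-negative integer", call. = FALSE)
  }
  b <- chain$b_levels
  r <- r_levels(chain)
  p <- r / (1 + r)
  q <- 1 - p
  v <- p0_vector(chain)
  for (step in seq_len(x)) {
    trans <- v[seq_len(b - 1L)]
    nxt <- numeric(b)
    nxt[seq_len(b - 1L)] <- p * trans
    nxt[2L:b] <- nxt[2L:b] + q * trans
    nxt[b] <- nxt[b] + v[b]
    v <- nxt
  }
  v
}

#' Closed-form mean and variance of cycles to failure
#'
#' For a chain started as a point mass at level 1, the time to absorption is
#' the sum of independent per-level holding times, giving
#' `E[Nf] = sum_j (1 + r_j)` and `var[Nf] = sum_j r_j (1 + r_j)` over the
#' transient levels `j = 1 .. b - 1`.
#'
#' @param chain A [damage_chain()] with the default pristine initial state.
#' @return A [life_statistics()] object (units: cycles).
#' @export
chain_moments <- function(chain) {
  stopifnot(inherits(chain, "damage_chain"))
  if (!pristine_start(chain)) {
    stop("closed-form moments require a point-mass initial state at level 1; ",
         "use simulate_chain() for a general initial distribution",
         call. = FALSE)
  }
  if (chain$uniform_r) {
    m <- chain$b_levels - 1
    life_statistics(mean_life = m * (1 + chain$r),
                    var_life = m * chain$r * (1 + chain$r))
  } else {
    r <- chain$r
    life_statistics(mean_life = sum(1 + r), var_life = sum(r * (1 + r)))
  }
}

#' Mean and variance of fatigue life
#'
#' Lightweight container for the first two moments of cycles to failure.
#'
#' @param mean_life Mean life in cycles (> 0).
#' @param var_life Variance of life in cycles^2 (>= 0).
#' @return An object of class `life_statistics`.
#' @export
life_statistics <- function(mean_life, var_life) {
  if (!is.numeric(mean_life) || length(mean_life) != 1L ||
      !is.finite(mean_life) || mean_life <= 0) {
    stop("`mean_life` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(var_life) || length(var_life) != 1L ||
      !is.finite(var_life) || var_life < 0) {
    stop("`var_life` must be a single non-negative number", call. = FALSE)
  }
  structure(list(mean_life = mean_life, var_life = var_life),
            class = "life_statistics")
}

#' @export
print.life_statistics <- function(x, ...) {
  cat("Fatigue life statistics\n")
  cat(sprintf("  mean life: %.6g cycles (%.4g million)\n",
              x$mean_life, x$mean_life / 1e6))
  cat(sprintf("  variance : %.6g cycles^2 (%.4g million^2)\n",
              x$var_life, x$var_life / 1e12))
  invisible(x)
}

#' Calibrate a uniform-ratio damage chain from life moments
#'
#' Moment matching: a uniform chain with `m = b - 1` transient levels has
#' mean `m (1 + r)` and variance `m r (1 + r)`, so `r = var/mean` and
#' `m = mean / (1 + r)`. After rounding `m` to an integer, `r` is re-solved
#' as `mean/m - 1` so the mean is preserved exactly; the achieved variance
#' (approximate because of the rounding) is reported as an attribute.
#'
#' @param target A [life_statistics()] object (moments in cycles).
#' @return A uniform-`r` [damage_chain()] with attributes
#'   `achieved_moments` (a `life_statistics`) and `target_moments`.
#' @export
calibrate_chain <- function(target) {
  stopifnot(inherits(target, "life_statistics"))
  mean <- target$mean_life
  var <- target$var_life
  if (mean <= 0) stop("target mean life must be > 0", call. = FALSE)
  r0 <- var / mean
  m <- max(1, round(mean / (1 + r0)))
  r <- max(mean / m - 1, 0)
  chain <- damage_chain(b_levels = m + 1, r = r)
  attr(chain, "achieved_moments") <- chain_moments(chain)
  attr(chain, "target_moments") <- target
  chain
}

#' Probability of failure by x cycles
#'
#' For a uniform-ratio chain the number of cycles to absorption is
#' `Nf = (b - 1) + M` where `M` is negative binomial with size `b - 1` and
#' success (jump) probability `q = 1/(1 + r)`: absorption needs exactly
#' `b - 1` jumps, and `M` counts the interleaved stays. The CDF is evaluated
#' through [stats::pnbinom()] (the regularized incomplete beta function),
#' which is numerically stable for the very large level counts that arise
#' from megacycle-scale lives. Equals the last entry of
#' [damage_state_distribution()].
#'
#' @param chain A uniform-`r` [damage_chain()].
#' @param x Cycle count(s), >= 0; non-integers are floored.
#' @return Failure probabilities in `[0, 1]`, same length as `x`.
#' @export
failure_probability <- function(chain, x) {
  stopifnot(inherits(chain, "damage_chain"))
  if (!chain$uniform_r) {
    stop("closed-form failure probability requires a uniform stay/jump ratio",
         call. = FALSE)
  }
  if (any(x < 0)) stop("cycle counts must be >= 0", call. = FALSE)
  b <- chain$b_levels
  q <- 1 / (1 + chain$r)
  k <- floor(x) - (b - 1)
  out <- numeric(length(x))
  ok <- k >= 0
  # prob = 1 (r = 0) degenerates to a point mass at zero extra stays
  out[ok] <- stats::pnbinom(k[ok], size = b - 1, prob = q)
  out
}

#' Failure-probability curve over a cycle grid
#'
#' @param chain A uniform-`r` [damage_chain()].
#' @param x_grid Sorted ascending vector of cycle counts.
#' @return A `failure_curve`: data frame with columns `cycles` and
#'   `probability` (non-decreasing).
#' @export
failure_curve <- function(chain, x_grid) {
  if (is.unsorted(x_grid, strictly = FALSE)) {
    stop("`x_grid` must be sorted ascending", call. = FALSE)
  }
  curve <- data.frame(cycles = x_grid,
                      probability = failure_probability(chain, x_grid))
  class(curve) <- c("failure_curve", "data.frame")
  curve
}

#' Simulate absorption times of a damage chain
#'
#' Draws cycles-to-failure realisations for validation against the closed
#' forms. `method = "geometric"` samples each transient level's holding time
#' as `1 + Geometric(q_j)` and sums them (exact, fast for any level count);
#' `method = "walk"` steps the chain one Bernoulli trial at a time (slow,
#' only sensible for small chains, useful as a fully mechanistic oracle).
#' The start level is drawn from the chain's initial distribution.
#'
#' @param chain A [damage_chain()].
#' @param n Number of walks.
#' @param seed Integer RNG seed.
#' @param method `"geometric"` (default) or `"walk"`.
#' @return Integer-valued numeric vector of `n` absorption times (cycles).
#' @export
simulate_chain <- function(chain, n, seed = 1L,
                           method = c("geometric", "walk")) {
  stopifnot(inherits(chain, "damage_chain"))
  method <- match.arg(method)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  b <- chain$b_levels
  r <- r_levels(chain)
  q <- 1 / (1 + r)
  set.seed(seed)
  start <- if (is.null(chain$p0)) {
    rep(1L, n)
  } else {
    sample.int(b - 1L, n, replace = TRUE, prob = chain$p0[-b])
  }
  if (method == "geometric") {
    out <- numeric(n)
    for (j in seq_len(b - 1L)) {
      active <- start <= j
      na <- sum(active)
      if (na > 0L) {
        out[active] <- out[active] + 1 + stats::rgeom(na, prob = q[j])
      }
    }
    out
  } else {
    vapply(start, function(s) {
      lvl <- s
      cycles <- 0
      while (lvl < b) {
        cycles <- cycles + 1
        if (stats::runif(1) <= q[lvl]) lvl <- lvl + 1L
      }
      cycles
    }, numeric(1))
  }
}
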