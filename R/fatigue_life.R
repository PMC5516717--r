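#' Cyclic and strain-life fatigue properties
#'
#' Bundles the Ramberg-Osgood cyclic hardening constants and the
#' Coffin-Basquin-Manson strain-life constants. Defaults are literature-style
#' values for wrought Ti6Al4V, the alloy of commercial implant bodies; they
#' are placeholders in the sense that cyclic test data for a specific implant
#' lot should override them.
#'
#' @param k Cyclic strength coefficient, MPa (> 0).
#' @param n_prime Cyclic strain-hardening exponent, dimensionless (0, 1).
#' @param sigma_f_prime Fatigue strength coefficient, MPa (> 0).
#' @param epsilon_f_prime Fatigue ductility coefficient, dimensionless (>= 0).
#' @param b_exp Fatigue strength (Basquin) exponent, < 0.
#' @param c_exp Fatigue ductility (Coffin-Manson) exponent, < 0.
#' @return An object of class `fatigue_properties`.
#' @export
fatigue_properties <- function(k = 1100, n_prime = 0.05,
                               sigma_f_prime = 2030, epsilon_f_prime = 0.841,
                               b_exp = -0.104, c_exp = -0.69) {
  stopifnot(k > 0, n_prime > 0, n_prime < 1, sigma_f_prime > 0,
            epsilon_f_prime >= 0, b_exp < 0, c_exp < 0)
  structure(list(k = k, n_prime = n_prime, sigma_f_prime = sigma_f_prime,
                 epsilon_f_prime = epsilon_f_prime, b_exp = b_exp,
                 c_exp = c_exp),
            class = "fatigue_properties")
}

#' @export
print.fatigue_properties <- function(x, ...) {
  cat("Fatigue properties (cyclic + strain-life)\n")
  cat(sprintf("  Ramberg-Osgood: k = %g MPa, n' = %g\n", x$k, x$n_prime))
  cat(sprintf("  strain-life: sigma_f' = %g MPa, eps_f' = %g, b = %g, c = %g\n",
              x$sigma_f_prime, x$epsilon_f_prime, x$b_exp, x$c_exp))
  invisible(x)
}

#' Neuber elastic-plastic notch correction
#'
#' Given the elastic stress `sigma_el` from a linear analysis at a stress
#' concentrator, estimates the local elastic-plastic stress by solving
#'
#'   sigma_ep/E + (sigma_ep/k)^(1/n') - eps_el^2 E / sigma_ep = 0,
#'
#' with `eps_el = sigma_el / E`, i.e. Neuber's hyperbola
#' `sigma_ep * eps_ep = sigma_el * eps_el` intersected with the
#' Ramberg-Osgood cyclic curve. The residual is strictly increasing in
#' `sigma_ep` on (0, sigma_el], non-negative at `sigma_el`, and tends to
#' -Inf at 0+, so a unique bracketed root exists; it is found with
#' [stats::uniroot()] (Brent). The elastic-plastic strain is recovered from
#' the hyperbola.
#'
#' @param sigma_el Elastic stress at the concentrator, MPa (> 0).
#' @param E Elastic modulus, MPa.
#' @param props A [fatigue_properties()] object.
#' @param tol Relative root tolerance (default 1e-10).
#' @return List of class `neuber_state` with `sigma_ep` (MPa), `eps_ep`
#'   (dimensionless) and the `residual` at the root.
#' @export
neuber_solve <- function(sigma_el, E, props, tol = 1e-10) {
  stopifnot(inherits(props, "fatigue_properties"), sigma_el > 0, E > 0)
  eps_el <- sigma_el / E
  inv_n <- 1 / props$n_prime
  # eps_el^2 E / s = sigma_el^2 / (E s); grouping the elastic terms as
  # (s^2 - sigma_el^2)/(E s) avoids the catastrophic cancellation that
  # otherwise drowns the tiny plastic term near the elastic limit
  resid <- function(s) {
    (s - sigma_el) * (s + sigma_el) / (E * s) +
      exp(inv_n * (log(s) - log(props$k)))
  }
  lo <- sigma_el * 1e-8
  hi <- sigma_el
  flo <- resid(lo)
  fhi <- resid(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo > 0 || fhi < 0) {
    stop(sprintf(paste0("no sign change when bracketing the Neuber root: ",
                        "residual(%.3g) = %.3g, residual(%.3g) = %.3g"),
                 lo, flo, hi, fhi), call. = FALSE)
  }
  root <- stats::uniroot(resid, lower = lo, upper = hi,
                         f.lower = flo, f.upper = fhi,
                         tol = tol * sigma_el)
  sigma_ep <- root$root
  structure(list(sigma_ep = sigma_ep,
                 eps_ep = sigma_el * eps_el / sigma_ep,
                 residual = resid(sigma_ep)),
            class = "neuber_state")
}

#' Invert the Coffin-Basquin-Manson strain-life relation
#'
#' Solves for the fatigue life `Nf` in
#'
#'   delta_eps_ep / 2 = (sigma_f'/E) (2 Nf)^b + eps_f' (2 Nf)^c,
#'
#' whose right-hand side is strictly decreasing in `2 Nf` (both exponents are
#' negative). The root is bracketed in reversals `2 Nf` on
#' `10^log2n_range` and found by Brent's method on `log10(2 Nf)`.
#'
#' @param delta_eps_ep Elastic-plastic strain range at the crack-initiation
#'   site, dimensionless (> 0).
#' @param E Elastic modulus, MPa.
#' @param props A [fatigue_properties()] object.
#' @param tol Tolerance on `log10(2 Nf)` (default 1e-12).
#' @param log2n_range Bracket for `log10(2 Nf)`, default `c(0, 12)`.
#' @return Fatigue life `Nf` in cycles (real-valued; rounding to integer
#'   cycles is deferred to the damage-chain calibration).
#' @export
coffin_manson_life <- function(delta_eps_ep, E, props, tol = 1e-12,
                               log2n_range = c(0, 12)) {
  stopifnot(inherits(props, "fatigue_properties"), E > 0)
  if (delta_eps_ep <= 0) stop("`delta_eps_ep` must be > 0", call. = FALSE)
  amp <- delta_eps_ep / 2
  g <- function(l) {
    (props$sigma_f_prime / E) * 10^(l * props$b_exp) +
      props$epsilon_f_prime * 10^(l * props$c_exp) - amp
  }
  g_lo <- g(log2n_range[1])
  g_hi <- g(log2n_range[2])
  if (g_lo < 0) {
    stop(sprintf(paste0("strain amplitude %.4g exceeds the strain-life curve ",
                        "at 2Nf = 10^%g (life below the bracket)"),
                 amp, log2n_range[1]), call. = FALSE)
  }
  if (g_hi > 0) {
    stop(sprintf(paste0("strain amplitude %.4g is below the strain-life curve ",
                        "at 2Nf = 10^%g (life beyond the bracket)"),
                 amp, log2n_range[2]), call. = FALSE)
  }
  root <- stats::uniroot(g, lower = log2n_range[1], upper = log2n_range[2],
                         f.lower = g_lo, f.upper = g_hi, tol = tol)
  10^root$root / 2
}

#' First-order moments of fatigue life through the full damage map
#'
#' Composes elastic stress at the critical point -> Neuber correction ->
#' Coffin-Basquin-Manson inversion into a single map
#' `Nf(E_titanium, load)`, and propagates the two random inputs by the
#' first-order second-moment method: the mean life is the composition
#' evaluated at the mean inputs, and the variance is
#' `sum_i (dNf/dX_i)^2 sd_i^2` with central finite differences on the
#' composition.
#'
#' The load cycle is taken as zero-to-peak (one mastication event loads and
#' fully unloads the implant), and the strain range entering the strain-life
#' relation is `delta_eps_factor * eps_ep(peak)`; the default factor of 2
#' treats the peak elastic-plastic strain as the strain amplitude.
#'
#' @param surrogate Function `(E_titanium, load_magnitude) -> elastic von
#'   Mises stress (MPa)` at the critical point, e.g. built from
#'   [implant_surrogate()] via [surrogate_response()]. The critical element
#'   must be held fixed across perturbations (the surrogate object does this).
#' @param E_rv [random_variable()] for the titanium elastic modulus (MPa).
#' @param load_rv [random_variable()] for the load magnitude (N).
#' @param props A [fatigue_properties()] object.
#' @param delta_eps_factor Strain range as a multiple of the peak
#'   elastic-plastic strain (default 2; configurable for other cycle shapes).
#' @param rel_step Relative central finite-difference step (default 1e-3).
#' @param log2n_range Bracket passed to [coffin_manson_life()].
#' @return A [life_statistics()] with attribute `gradients` (dNf/dE,
#'   dNf/dload) and `nf0` (deterministic mean-input life).
#' @export
life_moments <- function(surrogate, E_rv, load_rv, props,
                         delta_eps_factor = 2, rel_step = 1e-3,
                         log2n_range = c(0, 12)) {
  stopifnot(is.function(surrogate),
            inherits(E_rv, "random_variable"),
            inherits(load_rv, "random_variable"),
            inherits(props, "fatigue_properties"))
  nf <- function(E, load) {
    sigma_el <- surrogate(E, load)
    if (!is.finite(sigma_el) || sigma_el <= 0) {
      stop("surrogate returned a non-positive or non-finite elastic stress",
           call. = FALSE)
    }
    st <- neuber_solve(sigma_el, E, props)
    coffin_manson_life(delta_eps_factor * st$eps_ep, E, props,
                       log2n_range = log2n_range)
  }
  E0 <- E_rv$mean
  L0 <- load_rv$mean
  nf0 <- nf(E0, L0)
  hE <- rel_step * E0
  hL <- rel_step * L0
  gE <- (nf(E0 + hE, L0) - nf(E0 - hE, L0)) / (2 * hE)
  gL <- (nf(E0, L0 + hL) - nf(E0, L0 - hL)) / (2 * hL)
  out <- life_statistics(mean_life = nf0,
                         var_life = (gE * E_rv$sd)^2 + (gL * load_rv$sd)^2)
  attr(out, "gradients") <- c(dNf_dE = gE, dNf_dload = gL)
  attr(out, "nf0") <- nf0
  out
}
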