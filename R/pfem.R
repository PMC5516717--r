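#' Random input variable (mean and standard deviation)
#'
#' First-order second-moment analysis characterises each random input by its
#' first two moments only. A warning is emitted when the coefficient of
#' variation exceeds 0.3, where the first-order Taylor expansion underlying
#' the propagation loses validity.
#'
#' @param name Variable name; recognised model parameters are
#'   `"titanium_E"` (MPa) and `"load_magnitude"` (N).
#' @param mean Mean value in the physical units of the quantity.
#' @param sd Standard deviation, same units (>= 0).
#' @return An object of class `random_variable` with a `cov` field
#'   (coefficient of variation).
#' @export
random_variable <- function(name, mean, sd) {
  stopifnot(is.character(name), length(name) == 1L, sd >= 0)
  cov <- if (mean != 0) sd / abs(mean) else Inf
  if (is.finite(cov) && cov > 0.3) {
    warning(sprintf(paste0("random variable '%s' has CoV %.2f > 0.3; ",
                           "first-order propagation may be inaccurate"),
                    name, cov), call. = FALSE)
  }
  structure(list(name = name, mean = mean, sd = sd, cov = cov),
            class = "random_variable")
}

#' @export
print.random_variable <- function(x, ...) {
  cat(sprintf("Random variable '%s': mean %g, sd %g (CoV %.3g)\n",
              x$name, x$mean, x$sd, x$cov))
  invisible(x)
}

# draw truncated-at-zero Gaussians by rejection (caller sets the seed)
rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Precompute a fast stress surrogate at the critical point
#'
#' Splits the global stiffness into the titanium part (linear in the titanium
#' modulus) and the fixed bone part, caches the symbolic Cholesky analysis,
#' and locates the critical element at the nominal inputs. Subsequent
#' evaluations at perturbed or sampled inputs reuse the cached structure and
#' hold the critical element fixed, as required for finite-difference
#' sensitivities.
#'
#' @param mesh An implant mesh from [build_mesh()].
#' @param materials Named region->[elastic_material()] list (titanium entry
#'   gives the nominal modulus).
#' @param load A [load_case()] fixing the load direction.
#' @param load_magnitude Nominal resultant magnitude, N; defaults to the
#'   load case resultant.
#' @param region,metric Passed to [find_critical_point()] to pin the
#'   critical element.
#' @return An object of class `implant_surrogate`.
#' @export
implant_surrogate <- function(mesh, materials, load,
                              load_magnitude = load$resultant,
                              region = "titanium",
                              metric = "von_mises") {
  stopifnot(inherits(mesh, "implant_mesh"))
  ti_elems <- which(mesh$region == "titanium")
  other_elems <- which(mesh$region != "titanium")
  nu_ti <- materials$titanium$poisson_ratio
  unit_ti <- list(titanium = elastic_material(1, nu_ti))
  Kt <- assemble_stiffness(mesh, unit_ti, ti_elems)
  Kb <- assemble_stiffness(mesh, materials, other_elems)
  f_unit <- traction_forces(mesh, fx = load$transverse / load$resultant,
                            fy = -load$axial / load$resultant)
  free <- setdiff(seq_along(f_unit), model_fixed_dofs(mesh))
  Kt_ff <- Kt[free, free, drop = FALSE]
  Kb_ff <- Kb[free, free, drop = FALSE]
  E0 <- materials$titanium$youngs_modulus
  K0 <- Matrix::forceSymmetric(E0 * Kt_ff + Kb_ff)
  chol0 <- Matrix::Cholesky(K0, LDL = FALSE)
  model <- list(mesh = mesh, materials = materials, load = load,
                Kt_ff = Kt_ff, Kb_ff = Kb_ff, f_free = f_unit[free],
                free = free, ndof = length(f_unit), chol = chol0,
                nominal_E = E0, nominal_load = load_magnitude,
                critical = NULL)
  class(model) <- "implant_surrogate"
  u <- surrogate_displacements(model, E0, load_magnitude)
  field <- element_stresses_for(model, u, E0)
  crit_df <- data.frame(von_mises = field[, "von_mises"],
                        max_principal = field[, "max_principal"])
  in_region <- which(mesh$region == region)
  model$critical <- list(
    element = in_region[which.max(crit_df[[metric]][in_region])],
    metric = metric, region = region)
  model$critical$value <- crit_df[[metric]][model$critical$element]
  model
}

surrogate_displacements <- function(model, E_titanium, load_magnitude) {
  K <- Matrix::forceSymmetric(E_titanium * model$Kt_ff + model$Kb_ff)
  ch <- Matrix::update(model$chol, K)
  u <- numeric(model$ndof)
  u[model$free] <- as.vector(
    Matrix::solve(ch, load_magnitude * model$f_free))
  u
}

# full element stress table with the titanium modulus overridden
element_stresses_for <- function(model, u, E_titanium) {
  mats <- model$materials
  mats$titanium <- elastic_material(E_titanium,
                                    mats$titanium$poisson_ratio)
  element_stresses(model$mesh, mats, u)
}

# stress tensor at one element for given displacements
element_stress_at <- function(model, u, E_titanium, element) {
  mesh <- model$mesh
  mat <- model$materials[[mesh$region[element]]]
  E <- if (mesh$region[element] == "titanium") E_titanium else
    mat$youngs_modulus
  geo <- element_geometry(mesh$nodes,
                          mesh$elements[element, , drop = FALSE])
  B <- b_matrix(geo$b[1, ], geo$c[1, ], geo$area[1])
  nd <- mesh$elements[element, ]
  dofs <- c(2L * nd[1] - 1L, 2L * nd[1], 2L * nd[2] - 1L, 2L * nd[2],
            2L * nd[3] - 1L, 2L * nd[3])
  s <- as.vector(plane_strain_D(E, mat$poisson_ratio) %*% (B %*% u[dofs]))
  szz <- mat$poisson_ratio * (s[1] + s[2])
  list(sxx = s[1], syy = s[2], sxy = s[3], szz = szz,
       von_mises = von_mises(s[1], s[2], s[3], szz), E = E)
}

#' Evaluate the surrogate response at given inputs
#'
#' Elastic von Mises stress or equivalent elastic strain at the critical
#' element pinned by [implant_surrogate()] (held fixed across input
#' perturbations).
#'
#' @param model An `implant_surrogate`.
#' @param E_titanium Titanium Young's modulus, MPa.
#' @param load_magnitude Load resultant magnitude, N.
#' @param response `"von_mises_stress"` (MPa) or `"von_mises_strain"`.
#' @return Scalar response value.
#' @export
surrogate_response <- function(model, E_titanium, load_magnitude,
                               response = c("von_mises_stress",
                                            "von_mises_strain")) {
  stopifnot(inherits(model, "implant_surrogate"))
  response <- match.arg(response)
  u <- surrogate_displacements(model, E_titanium, load_magnitude)
  s <- element_stress_at(model, u, E_titanium, model$critical$element)
  if (!is.finite(s$von_mises)) {
    stop("non-finite response at the evaluated inputs", call. = FALSE)
  }
  if (response == "von_mises_stress") s$von_mises else s$von_mises / s$E
}

# map a random variable name to a surrogate parameter slot
rv_slot <- function(name) {
  if (name %in% c("titanium_E", "E_titanium", "E")) return("E")
  if (name %in% c("load_magnitude", "load")) return("load")
  stop(sprintf("random variable '%s' does not map to a model parameter ",
               name), call. = FALSE)
}

#' Gradient of the surrogate response with respect to the random inputs
#'
#' Central finite differences with a relative step about the mean of each
#' random variable; the critical element stays pinned at its mean-input
#' location.
#'
#' @param model An `implant_surrogate`.
#' @param rvs List of [random_variable()]s (`titanium_E`,
#'   `load_magnitude`).
#' @param response Response name, see [surrogate_response()].
#' @param rel_step Relative finite-difference step (default 1e-3).
#' @return Named numeric gradient vector (response units per RV unit).
#' @export
response_gradient <- function(model, rvs,
                              response = c("von_mises_stress",
                                           "von_mises_strain"),
                              rel_step = 1e-3) {
  response <- match.arg(response)
  at <- function(E, load) surrogate_response(model, E, load, response)
  means <- c(E = model$nominal_E, load = model$nominal_load)
  for (rv in rvs) means[rv_slot(rv$name)] <- rv$mean
  grad <- vapply(rvs, function(rv) {
    slot <- rv_slot(rv$name)
    h <- rel_step * abs(rv$mean)
    up <- means; up[slot] <- up[slot] + h
    dn <- means; dn[slot] <- dn[slot] - h
    g <- (at(up[["E"]], up[["load"]]) - at(dn[["E"]], dn[["load"]])) / (2 * h)
    if (!is.finite(g)) {
      stop("non-finite response at a perturbed point", call. = FALSE)
    }
    g
  }, numeric(1))
  names(grad) <- vapply(rvs, `[[`, character(1), "name")
  grad
}

#' First-order second-moment propagation
#'
#' For mutually independent inputs, the first-order mean is the response at
#' the mean inputs and the variance is the sum of squared
#' gradient-times-standard-deviation contributions.
#'
#' @param g0 Response at the mean inputs.
#' @param gradient Gradient vector from [response_gradient()] (same order
#'   as `rvs`).
#' @param rvs List of [random_variable()]s.
#' @return List with `mean` and `variance`.
#' @export
fosm_moments <- function(g0, gradient, rvs) {
  sds <- vapply(rvs, `[[`, numeric(1), "sd")
  list(mean = g0, variance = sum((gradient * sds)^2))
}

#' Stress and strain statistics at the critical point
#'
#' Runs the FOSM propagation for both the von Mises stress and the
#' equivalent elastic strain at the pinned critical element.
#'
#' @param model An `implant_surrogate`.
#' @param rvs List of [random_variable()]s.
#' @param rel_step Relative finite-difference step.
#' @return An object of class `stress_point_stats` with fields
#'   `mean_stress` (MPa), `var_stress` (MPa^2), `mean_strain`, `var_strain`
#'   and `element`.
#' @export
pfem_stats <- function(model, rvs, rel_step = 1e-3) {
  means <- c(E = model$nominal_E, load = model$nominal_load)
  for (rv in rvs) means[rv_slot(rv$name)] <- rv$mean
  s0 <- surrogate_response(model, means[["E"]], means[["load"]],
                           "von_mises_stress")
  e0 <- surrogate_response(model, means[["E"]], means[["load"]],
                           "von_mises_strain")
  gs <- response_gradient(model, rvs, "von_mises_stress", rel_step)
  ge <- response_gradient(model, rvs, "von_mises_strain", rel_step)
  ms <- fosm_moments(s0, gs, rvs)
  me <- fosm_moments(e0, ge, rvs)
  structure(list(mean_stress = ms$mean, var_stress = ms$variance,
                 mean_strain = me$mean, var_strain = me$variance,
                 element = model$critical$element),
            class = "stress_point_stats")
}

#' @export
print.stress_point_stats <- function(x, ...) {
  cat("Critical-point stress/strain statistics (FOSM)\n")
  cat(sprintf("  element %d\n", x$element))
  cat(sprintf("  stress: mean %.4g MPa, sd %.4g MPa\n",
              x$mean_stress, sqrt(x$var_stress)))
  cat(sprintf("  strain: mean %.4g, sd %.4g\n",
              x$mean_strain, sqrt(x$var_strain)))
  invisible(x)
}

#' Monte Carlo moments of a model response (validation oracle)
#'
#' Samples the random inputs as independent Gaussians truncated at zero,
#' evaluates the response for each draw, and returns empirical moments with
#' standard errors. The FOSM path exists precisely to avoid this simulation;
#' it is provided as the independent check.
#'
#' @param model Either an `implant_surrogate` (evaluated via
#'   [surrogate_response()]) or a function taking one argument per random
#'   variable, in the order of `rvs`.
#' @param rvs List of [random_variable()]s.
#' @param n Number of draws (>= 2).
#' @param seed Integer RNG seed.
#' @param response Response name when `model` is a surrogate.
#' @return List with `mean`, `variance`, `se_mean`, `se_variance`, `n`.
#' @export
monte_carlo_moments <- function(model, rvs, n, seed = 1L,
                                response = "von_mises_stress") {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be >= 2", call. = FALSE)
  set.seed(seed)
  draws <- vapply(rvs, function(rv) rtrunc0(n, rv$mean, rv$sd),
                  numeric(n))
  draws <- matrix(draws, nrow = n)
  if (inherits(model, "implant_surrogate")) {
    slots <- vapply(rvs, function(rv) rv_slot(rv$name), character(1))
    vals <- vapply(seq_len(n), function(i) {
      E <- model$nominal_E
      load <- model$nominal_load
      for (k in seq_along(rvs)) {
        if (slots[k] == "E") E <- draws[i, k] else load <- draws[i, k]
      }
      surrogate_response(model, E, load, response)
    }, numeric(1))
  } else if (is.function(model)) {
    vals <- vapply(seq_len(n), function(i) {
      do.call(model, as.list(draws[i, ]))
    }, numeric(1))
  } else {
    stop("`model` must be an implant_surrogate or a function", call. = FALSE)
  }
  v <- stats::var(vals)
  m4 <- mean((vals - mean(vals))^4)
  se_var <- sqrt(pmax(0, m4 - (n - 3) / (n - 1) * v^2) / n)
  list(mean = mean(vals), variance = v,
       se_mean = stats::sd(vals) / sqrt(n), se_variance = se_var, n = n)
}
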