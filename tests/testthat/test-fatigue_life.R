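test_that("Neuber correction reduces to the elastic solution when plasticity is negligible", {
  props <- fatigue_properties(k = 1e9, n_prime = 0.05)
  st <- neuber_solve(100, E = 1e5, props)
  expect_equal(st$sigma_ep, 100, tolerance = 1e-4)
  expect_equal(st$eps_ep, 100 / 1e5, tolerance = 1e-4)
})

test_that("Neuber root matches a dense bisection oracle and its invariants", {
  props <- fatigue_properties(k = 1100, n_prime = 0.05)
  E <- 110e3
  st <- neuber_solve(600, E, props)
  oracle <- neuber_bisect_oracle(600, E, k = 1100, n_prime = 0.05)
  expect_equal(st$sigma_ep, oracle, tolerance = 1e-8)
  expect_lt(st$sigma_ep, 600) # elastic-plastic stress below elastic

  # residual of the governing equation at the root
  resid <- st$sigma_ep / E + (st$sigma_ep / 1100)^(1 / 0.05) -
    (600 / E)^2 * E / st$sigma_ep
  expect_lt(abs(resid), 1e-9)
  # Neuber hyperbola sigma*eps = const
  expect_equal(st$sigma_ep * st$eps_ep, 600 * (600 / E), tolerance = 1e-9)

  # monotone in the elastic driving stress
  expect_lt(neuber_solve(300, E, props)$sigma_ep, st$sigma_ep)
})

test_that("strain-life inversion reproduces the one-term closed forms", {
  # Basquin only: 2Nf = ((delta_eps * E) / (2 sigma_f'))^(1/b)
  props <- fatigue_properties(sigma_f_prime = 2000, epsilon_f_prime = 0,
                              b_exp = -0.1, c_exp = -0.5)
  nf <- coffin_manson_life(0.004, E = 1e5, props)
  expect_equal(nf, 5e9, tolerance = 1e-3)

  # Coffin-Manson only: (2Nf)^c = amp / eps_f'
  props <- fatigue_properties(sigma_f_prime = 1e-12, epsilon_f_prime = 0.5,
                              b_exp = -0.1, c_exp = -0.5)
  nf <- coffin_manson_life(0.01, E = 1e5, props)
  expect_equal(nf, 5000, tolerance = 1e-3)
})

test_that("two-term strain-life inversion agrees with a grid-scan oracle and round-trips", {
  props <- fatigue_properties() # Ti6Al4V-style defaults
  E <- 100e3
  for (delta in c(0.02, 0.008, 0.0045)) {
    nf <- coffin_manson_life(delta, E, props)
    expect_equal(nf, cm_grid_oracle(delta, E, props), tolerance = 1e-4)
    # evaluating the strain-life relation at the root recovers the amplitude
    rhs <- (props$sigma_f_prime / E) * (2 * nf)^props$b_exp +
      props$epsilon_f_prime * (2 * nf)^props$c_exp
    expect_equal(rhs, delta / 2, tolerance = 1e-10)
  }
})

test_that("fatigue life is strictly decreasing in the strain range", {
  props <- fatigue_properties()
  set.seed(5)
  for (i in 1:15) {
    d1 <- stats::runif(1, 0.004, 0.05)
    d2 <- d1 * stats::runif(1, 1.01, 2)
    expect_gt(coffin_manson_life(d1, 1e5, props),
              coffin_manson_life(d2, 1e5, props))
  }
  expect_error(coffin_manson_life(20, 1e5, props), "exceeds")
  expect_error(coffin_manson_life(1e-9, 1e5, props), "beyond")
})

test_that("in the elastic limit the full chain reduces to Basquin", {
  # huge k suppresses plasticity, zero ductility term isolates Basquin
  props <- fatigue_properties(k = 1e9, n_prime = 0.05,
                              sigma_f_prime = 2030, epsilon_f_prime = 0,
                              b_exp = -0.104, c_exp = -0.69)
  E <- 1e5
  sigma_el <- 300
  st <- neuber_solve(sigma_el, E, props)
  nf <- coffin_manson_life(2 * st$eps_ep, E, props)
  basquin <- ((sigma_el / E) * E / props$sigma_f_prime)^(1 / props$b_exp) / 2
  expect_equal(nf, basquin, tolerance = 1e-3)
})

test_that("first-order life moments behave like a proper FOSM propagation", {
  props <- fatigue_properties()
  # toy surrogate: stress proportional to load, independent of E, scaled to
  # a strain range in the mid-life regime
  surrogate <- function(E, load) 2.5 * load
  E0 <- random_variable("titanium_E", 1e5, 0)
  L0 <- random_variable("load_magnitude", 118, 0)
  det <- life_moments(surrogate, E0, L0, props)
  expect_equal(det$var_life, 0)
  st <- neuber_solve(2.5 * 118, 1e5, props)
  expect_equal(det$mean_life,
               coffin_manson_life(2 * st$eps_ep, 1e5, props),
               tolerance = 1e-10)

  # variance shrinks monotonically with the input spread
  L1 <- random_variable("load_magnitude", 118, 6)
  L2 <- random_variable("load_magnitude", 118, 3)
  v1 <- life_moments(surrogate, E0, L1, props)$var_life
  v2 <- life_moments(surrogate, E0, L2, props)$var_life
  expect_gt(v1, v2)
  expect_gt(v1, 0)
})

test_that("life moments match Monte Carlo in the small-spread regime", {
  # Nf ~ load^(1/b) is a steep power law, so first-order propagation is
  # meaningful only for narrow input spreads (the method's stated domain);
  # there it must agree with simulation through the full composition
  props <- fatigue_properties()
  surrogate <- function(E, load) 2.5 * load
  E_rv <- random_variable("titanium_E", 1e5, 1e3)
  L_rv <- random_variable("load_magnitude", 118, 2)
  fosm <- life_moments(surrogate, E_rv, L_rv, props)
  nf_fun <- function(E, load) {
    st <- neuber_solve(surrogate(E, load), E, props)
    coffin_manson_life(2 * st$eps_ep, E, props)
  }
  mc <- monte_carlo_moments(nf_fun, list(E_rv, L_rv), n = 5000, seed = 42)
  expect_equal(fosm$mean_life, mc$mean, tolerance = 0.1)
  expect_equal(fosm$var_life, mc$variance, tolerance = 0.1)
})
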