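test_that("transition matrix has the unit-jump bidiagonal structure", {
  P <- transition_matrix(damage_chain(2, r = 1))
  expect_equal(P, matrix(c(0.5, 0, 0.5, 1), 2, 2))

  # r = 0: every transient level jumps deterministically
  P0 <- transition_matrix(damage_chain(4, r = 0))
  expect_equal(diag(P0), c(0, 0, 0, 1))
  expect_equal(P0[cbind(1:3, 2:4)], rep(1, 3))

  # row-stochastic for a spread of chains, incl. per-level ratios
  set.seed(11)
  for (b in c(2, 3, 7, 25)) {
    r <- stats::runif(b - 1, 0, 10)
    P <- transition_matrix(damage_chain(b, r = r))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-15)
    expect_true(all(P >= 0))
  }
})

test_that("state distribution evolves as p0 P^x and conserves probability", {
  ch <- damage_chain(3, r = 1)
  expect_equal(damage_state_distribution(ch, 0), c(1, 0, 0))
  expect_equal(damage_state_distribution(ch, 1), c(0.5, 0.5, 0))

  # dense matrix-power oracle
  ch <- damage_chain(4, r = 1)
  P <- transition_matrix(ch)
  Pp <- diag(4)
  for (i in 1:10) Pp <- Pp %*% P
  expect_lt(max(abs(damage_state_distribution(ch, 10) -
                      as.vector(c(1, 0, 0, 0) %*% Pp))), 1e-12)

  # conservation across steps, general initial distribution
  ch <- damage_chain(5, r = c(0.2, 3, 1, 0.5),
                     p0 = c(0.4, 0.3, 0.2, 0.1, 0))
  for (x in c(1, 5, 40)) {
    expect_equal(sum(damage_state_distribution(ch, x)), 1, tolerance = 1e-12)
  }
  expect_error(damage_state_distribution(ch, -1), "non-negative")
})

test_that("closed-form life moments match the per-level sums", {
  m <- chain_moments(damage_chain(2, r = 1))
  expect_equal(m$mean_life, 2)
  expect_equal(m$var_life, 2)

  r <- c(0.5, 2, 4)
  m <- chain_moments(damage_chain(4, r = r))
  expect_equal(m$mean_life, sum(1 + r))
  expect_equal(m$var_life, sum(r * (1 + r)))

  expect_error(chain_moments(damage_chain(3, 1, p0 = c(0.5, 0.5, 0))),
               "point-mass")
})

test_that("simulated absorption times agree with the closed-form moments", {
  ch <- damage_chain(6, r = 2)
  m <- chain_moments(ch)
  nf <- simulate_chain(ch, n = 2e4, seed = 42)
  se <- stats::sd(nf) / sqrt(length(nf))
  expect_lt(abs(mean(nf) - m$mean_life), 3 * se)

  # the step-by-step walk is distributionally identical to the
  # per-level geometric construction
  walk <- simulate_chain(damage_chain(3, r = 1), n = 4000, seed = 7,
                         method = "walk")
  m3 <- chain_moments(damage_chain(3, r = 1))
  expect_lt(abs(mean(walk) - m3$mean_life),
            3 * stats::sd(walk) / sqrt(length(walk)))
  expect_true(all(walk >= 2)) # at least b - 1 jumps
})

test_that("moment-matching calibration preserves the mean exactly", {
  # degenerate: zero variance gives a deterministic countdown chain
  ch <- calibrate_chain(life_statistics(4, 0))
  expect_equal(ch$b_levels, 5)
  expect_equal(ch$r, 0)
  expect_equal(failure_probability(ch, c(3, 4)), c(0, 1))

  # megacycle-scale target: ratio and level count as derived by hand
  ch <- calibrate_chain(life_statistics(1.03e8, 5.48e12))
  expect_equal(ch$b_levels - 1, 1936)
  expect_equal(ch$r, 5.3204e4, tolerance = 1e-4)
  m <- chain_moments(ch)
  expect_equal(m$mean_life, 1.03e8)
  expect_equal(m$var_life, 5.48e12, tolerance = 1e-3)

  # property: the mean always round-trips to 1e-9 relative
  set.seed(99)
  for (i in 1:20) {
    mean <- stats::runif(1, 2, 1e7)
    cov <- stats::runif(1, 0.001, 2)
    tgt <- life_statistics(mean, (cov * mean)^2)
    got <- chain_moments(calibrate_chain(tgt))
    expect_equal(got$mean_life, mean, tolerance = 1e-9)
  }
})

test_that("failure probability matches two independent oracles", {
  ch <- damage_chain(4, r = 1)
  # explicit negative-binomial sum written out by hand
  nb_sum <- sum(choose(0:7 + 2, 2) * 0.5^(3 + 0:7))
  expect_equal(failure_probability(ch, 10), nb_sum)
  expect_equal(failure_probability(ch, 10), 0.9453125)
  expect_equal(failure_probability(ch, 10),
               dense_power_failure_prob(ch, 10))

  # below b - 1 jumps absorption is impossible; r = 0 is a step
  expect_equal(failure_probability(ch, 2), 0)
  expect_equal(failure_probability(damage_chain(5, 0), c(3, 4, 9)),
               c(0, 1, 1))
})

test_that("failure probability is monotone and tends to one", {
  ch <- damage_chain(10, r = 4)
  x <- c(0, 9, 20, 50, 100, 500, 5000)
  p <- failure_probability(ch, x)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[length(p)], 1, tolerance = 1e-6)
})

test_that("failure curve is vectorised, monotone, and validates its grid", {
  ch <- damage_chain(6, r = 1.5)
  expect_error(failure_curve(ch, c(10, 5)), "sorted")
  curve <- failure_curve(ch, 0:40)
  expect_s3_class(curve, "failure_curve")
  expect_true(all(diff(curve$probability) >= 0))
  expect_true(all(curve$probability[curve$cycles < 5] == 0))
  expect_gt(curve$probability[nrow(curve)], curve$probability[1])
})

test_that("recalibration from simulated lifetimes recovers the chain", {
  truth <- damage_chain(40, r = 3)
  nf <- simulate_chain(truth, n = 1e5, seed = 12345)
  est <- calibrate_chain(life_statistics(mean(nf), stats::var(nf)))
  expect_lte(abs(est$b_levels - truth$b_levels), 1)
  expect_lt(abs(est$r - truth$r) / truth$r, 0.02)
})
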