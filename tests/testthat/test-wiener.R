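params_grid <- list(
  ddm_params(a = 0.5, zr = 0.5, v = 0, t0 = 0),
  ddm_params(a = 1, zr = 0.4, v = 1, t0 = 0),
  ddm_params(a = 2, zr = 0.5, v = 0.5, t0 = 0),
  ddm_params(a = 2.5, zr = 0.7, v = -2, t0 = 0),
  ddm_params(a = 1.5, zr = 0.3, v = 3, t0 = 0))

test_that("choice probability matches the closed form and its limits", {
  expect_equal(choice_probability(ddm_params(a = 2, zr = 0.5, v = 0)), 0.5)
  expect_equal(choice_probability(ddm_params(a = 2, zr = 0.3, v = 0)), 0.3)
  # a = 2, zr = 0.5, v = 0.5: (1 - e^-1)/(1 - e^-2) = 1/(1 + e^-1)
  expect_equal(choice_probability(ddm_params(a = 2, zr = 0.5, v = 0.5)),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  # continuity at v = 0 and monotonicity in v
  vs <- seq(-3, 3, by = 0.25)
  ps <- vapply(vs, function(v)
    choice_probability(ddm_params(a = 1.5, zr = 0.4, v = v)), 0.0)
  expect_true(all(diff(ps) > 0))
  expect_equal(choice_probability(ddm_params(a = 1.5, zr = 0.4, v = 1e-9)),
               0.4, tolerance = 1e-6)
  expect_gt(choice_probability(ddm_params(a = 1, zr = 0.5, v = 20)), 0.999)
})

test_that("defective densities integrate to boundary probabilities summing to 1", {
  for (p in params_grid) {
    up <- integrate(function(t) fpt_density(t, "upper", p), 0, Inf,
                    rel.tol = 1e-9)$value
    lo <- integrate(function(t) fpt_density(t, "lower", p), 0, Inf,
                    rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-4)
    expect_equal(up, choice_probability(p), tolerance = 1e-4)
  }
})

test_that("driftless symmetric mean first-passage time equals z(a - z)", {
  p <- ddm_params(a = 2, zr = 0.5, v = 0, t0 = 0)
  m <- integrate(function(t) t * (fpt_density(t, "upper", p) +
                                    fpt_density(t, "lower", p)),
                 0, Inf, rel.tol = 1e-9)$value
  expect_equal(m, 1.0, tolerance = 1e-4) # z(a-z) = 1*1
})

test_that("analytic CDF agrees with quadrature of the density in both series regimes", {
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.5, 2.5); w <- runif(1, 0.3, 0.7); v <- runif(1, -3, 3)
    t <- runif(1, 0.01, 2) * a^2 # spans both sides of the series switch
    p <- ddm_params(a = a, zr = w, v = v, t0 = 0)
    ref <- integrate(function(u) fpt_density(u, "lower", p), 0, t,
                     rel.tol = 1e-10, abs.tol = 1e-13)$value
    expect_equal(fpt_cdf(t, "lower", p), ref, tolerance = 1e-6)
  }
})

test_that("joint signed CDF reduces to the no-variability CDF and is monotone", {
  p0 <- ddm_params(a = 1.2, zr = 0.45, v = 0.8, t0 = 0.2)
  s <- c(-1.5, -0.7, -0.3, -0.21, 0.21, 0.4, 0.9, 2)
  direct <- ifelse(s < 0,
                   (1 - choice_probability(p0)) -
                     fpt_cdf(pmax(-s - 0.2, 1e-12), "lower", p0),
                   (1 - choice_probability(p0)) +
                     fpt_cdf(pmax(s - 0.2, 1e-12), "upper", p0))
  expect_equal(predicted_joint_cdf(p0, s), direct, tolerance = 1e-6)

  set.seed(5)
  for (i in 1:10) {
    p <- ddm_params(a = runif(1, 0.6, 2), zr = runif(1, 0.35, 0.65),
                    v = runif(1, -2, 2), t0 = runif(1, 0.1, 0.3),
                    sv = runif(1, 0, 0.5), sz = runif(1, 0, 0.2),
                    st0 = runif(1, 0, 0.1))
    g <- sort(runif(80, -2.5, 2.5))
    G <- predicted_joint_cdf(p, g)
    expect_true(!is.unsorted(G))
    expect_true(all(G >= 0 & G <= 1))
  }
  # limits: 1 at +infinity, lower-boundary probability just below zero
  p <- ddm_params(a = 1, zr = 0.5, v = 0.6, t0 = 0.2, sv = 0.3, sz = 0.1,
                  st0 = 0.08)
  expect_equal(predicted_joint_cdf(p, 30), 1, tolerance = 1e-8)
  set.seed(6)
  sim <- simulate_trials(1e5, p)
  expect_equal(predicted_joint_cdf(p, -1e-12), 1 - mean(sim$upper),
               tolerance = 0.01)
})

test_that("doubling quadrature nodes leaves the marginal CDF unchanged", {
  p <- ddm_params(a = 1, zr = 0.5, v = 0.6, t0 = 0.2, sv = 0.4, sz = 0.15,
                  st0 = 0.1)
  g <- seq(-2, 2.5, by = 0.05)
  expect_equal(predicted_joint_cdf(p, g, n_sv = 15, n_sz = 7, n_st0 = 7),
               predicted_joint_cdf(p, g, n_sv = 30, n_sz = 14, n_st0 = 14),
               tolerance = 1e-6)
})

test_that("simulator and analytic marginal distribution agree", {
  p <- ddm_params(a = 1, zr = 0.5, v = 0.6, t0 = 0.2, sv = 0.3, sz = 0.1,
                  st0 = 0.08)
  set.seed(42)
  sim <- simulate_trials(1e5, p)
  s <- sort(ifelse(sim$upper, sim$rt, -sim$rt))
  n <- length(s)
  G <- predicted_joint_cdf(p, s)
  ks <- max(abs(G - seq_len(n) / n), abs(G - (seq_len(n) - 1) / n))
  expect_lt(ks, 0.01)
})

test_that("halving the simulation step changes the mean RT by well under 1%", {
  p <- ddm_params(a = 1.5, zr = 0.5, v = 0.5, t0 = 0.2)
  set.seed(7)
  m1 <- mean(simulate_trials(4e4, p, dt = 5e-4)$rt)
  set.seed(7)
  m2 <- mean(simulate_trials(4e4, p, dt = 2.5e-4)$rt)
  expect_lt(abs(m1 - m2) / m1, 0.01)
})

test_that("illegal parameters are rejected", {
  expect_error(ddm_params(a = -1), "boundary separation")
  expect_error(ddm_params(zr = 0.9, sz = 0.3), "zr")
  expect_error(ddm_params(t0 = 0.05, st0 = 0.2), "t0")
  expect_error(fpt_density(-0.1, "upper", ddm_params()), "t must be")
  expect_error(choice_probability(ddm_params(sv = 0.2)), "closed form")
})
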