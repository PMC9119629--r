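test_that("rate matrix entries follow the binding/unbinding/killing scheme", {
  kin <- syt1_kinetics()
  Tm <- sensor_rate_matrix(kin, 0.1)
  expect_equal(Tm[2, 1], 5 * 0.0612 * 0.1)              # 0 -> 1 binding
  expect_equal(Tm[5, 6], 5 * 0.25^4 * 2.32)             # 5 -> 4 unbinding
  expect_equal(Tm[5, 6], 0.0453125)
  # columns conserve mass except the killed (fully bound) column
  expect_equal(colSums(Tm)[1:5], rep(0, 5), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(sum(Tm[, 6]), -6.0)
  # zero calcium removes all binding entries, leaves unbinding untouched
  T0 <- sensor_rate_matrix(kin, 0)
  expect_true(all(T0[cbind(2:6, 1:5)] == 0))
  expect_equal(T0[cbind(1:5, 2:6)], Tm[cbind(1:5, 2:6)])
  expect_error(sensor_rate_matrix(kin, -1), "non-negative")
})

test_that("constructors enforce kinetic invariants", {
  expect_error(sensor_kinetics(0, 1, 1, 0.5, 1), "positive integer")
  expect_error(sensor_kinetics(2, -1, 1, 0.5, 1), "positive")
  expect_error(sensor_kinetics(2, 1, 1, 0, 1), "coop_b")
  expect_error(sensor_kinetics(2, 1, 1, 1.5, 1), "coop_b")
  expect_s3_class(syt7_kinetics(), "sensor_kinetics")
})

test_that("equilibrium occupancies obey detailed balance", {
  kin <- syt1_kinetics()
  eq0 <- equilibrium_state(kin, 0)
  expect_equal(eq0, c(1, 0, 0, 0, 0, 0))
  eq <- equilibrium_state(kin, 0.1)
  expect_equal(sum(eq), 1, tolerance = 1e-14)
  # detailed-balance product oracle, assembled independently
  n <- 0:4
  pi_un <- c(1, cumprod((5 - n) * 0.0612 * 0.1 / ((n + 1) * 0.25^n * 2.32)))
  expect_equal(eq, pi_un / sum(pi_un), tolerance = 1e-13)
  expect_equal(eq[6], 1.3216e-7, tolerance = 1e-4)
})

test_that("quasi-stationary rates match independent oracles and limits", {
  kS <- syt1_kinetics()
  kA <- syt7_kinetics()
  expect_equal(quasi_stationary_rate(kS, 0), 0)
  s0 <- quasi_stationary_rate(kS, 0.1)
  a0 <- quasi_stationary_rate(kA, 0.1)
  # power iteration vs direct eigen-solve (two routes inside the package)
  expect_equal(s0, quasi_stationary_rate(kS, 0.1, method = "eigen"),
               tolerance = 1e-9)
  expect_equal(a0, quasi_stationary_rate(kA, 0.1, method = "eigen"),
               tolerance = 1e-9)
  # flux-corrected recursion oracle (independent route, helper)
  for (ca in c(0.01, 0.1, 1)) {
    expect_equal(quasi_stationary_rate(kS, ca), flux_recursion_rate(kS, ca),
                 tolerance = 1e-8)
    expect_equal(quasi_stationary_rate(kA, ca), flux_recursion_rate(kA, ca),
                 tolerance = 1e-8)
  }
  # flux-balance approximation neglects chain depression: an upper bound,
  # close but not exact (within ~5% here)
  fb <- flux_balance_rate(kS, 0.1)
  expect_gt(fb, s0)
  expect_lt(fb / s0 - 1, 0.05)
  # killing drains the top state: conditional rate below the equilibrium
  # readout gamma * pi_N at any concentration
  for (ca in c(0.01, 0.1, 1, 10)) {
    expect_lt(quasi_stationary_rate(kS, ca),
              kS$gamma_fuse * equilibrium_state(kS, ca)[6])
  }
})

test_that("spontaneous rates follow low-calcium power laws and saturate", {
  kS <- syt1_kinetics()
  kA <- syt7_kinetics()
  ca <- c(0.001, 0.002, 0.005, 0.01)
  rS <- vapply(ca, quasi_stationary_rate, 0, kin = kS)
  rA <- vapply(ca, quasi_stationary_rate, 0, kin = kA)
  slopeS <- coef(stats::lm(log(rS) ~ log(ca)))[[2]]
  slopeA <- coef(stats::lm(log(rA) ~ log(ca)))[[2]]
  expect_equal(slopeS, 5.00, tolerance = 0.02 / 5)
  expect_equal(slopeA, 2.00, tolerance = 0.02 / 2)
  # monotone increase, bounded by the fusion rate, approaching it
  grid <- 10^seq(-2, 5, by = 1)
  rates <- vapply(grid, quasi_stationary_rate, 0, kin = kS)
  expect_true(all(diff(rates) > 0))
  expect_true(all(rates < kS$gamma_fuse))
  expect_gt(rates[length(rates)], 0.99 * kS$gamma_fuse)
  expect_gt(quasi_stationary_rate(kA, 1e5), 0.99 * kA$gamma_fuse)
})

test_that("renormalized propagation conserves probability and matches the matrix exponential", {
  kin <- syt1_kinetics()
  for (ca in c(0.1, 100)) {
    tr <- ca_trace(rep(ca, 2001), dt = 0.005)
    run <- propagate_renormalized(kin, tr, dt = 0.005)
    expect_true(all(abs(rowSums(run$probs) - 1) < 1e-12))
    expect_true(all(run$probs >= 0 & run$probs <= 1))
    oracle <- expm_renorm_trajectory(kin, ca, 0.005, 2000,
                                     quasi_stationary_state(kin, ca))
    expect_lt(max(abs(run$probs - oracle)), 1e-6)
  }
  # conditional rate trace bounded and convergent to the stationary rate
  tr <- ca_trace(rep(0.1, 501), dt = 0.1)
  ct <- conditional_release_trace(kin, tr)
  expect_true(all(ct$rate_per_ms >= 0 & ct$rate_per_ms <= kin$gamma_fuse))
  qs <- quasi_stationary_rate(kin, 0.1)
  expect_lt(abs(ct$rate_per_ms[501] - qs) / qs, 0.001)
  # zero trace from the unbound state stays silent
  tr0 <- ca_trace(rep(0, 101), dt = 0.1)
  ct0 <- conditional_release_trace(kin, tr0, init = c(1, 0, 0, 0, 0, 0))
  expect_true(all(ct0$rate_per_ms == 0))
})

test_that("oversized steps are rejected with the offending time", {
  kin <- syt1_kinetics()
  tr <- ca_trace(rep(1000, 11), dt = 10)   # huge rates, huge step
  expect_error(propagate_renormalized(kin, tr, dt = 10), "t = ")
})

test_that("calcium impulse on a zero background decays single-exponentially", {
  kin <- syt1_kinetics()
  imp <- ca_impulse_trace(0, 100, 10, 30, dt = 0.1)
  run <- propagate_renormalized(kin, imp, dt = 0.005,
                                init = c(1, 0, 0, 0, 0, 0))
  r <- kin$gamma_fuse * run$probs[, 6]
  expect_gt(max(r), 0)
  it <- instantaneous_tau(run$time, r, 0)
  w <- run$time >= 10.6 & run$time <= 11.6
  taus <- it$tau_ms[w]
  expect_true(all(is.finite(taus)))
  expect_lt(diff(range(taus)) / mean(taus), 0.02)
})

test_that("generic CTMC step is linear, conservative and finds the two-state split", {
  R <- matrix(c(-0.3, 0.3, 0.1, -0.1), 2, 2)
  s <- c(0.9, 0.1)
  expect_equal(generic_ctmc_step(s, R, 0), s)
  s1 <- generic_ctmc_step(s, R, 0.01)
  expect_equal(sum(s1), sum(s), tolerance = 1e-12)
  for (i in 1:5000) s <- generic_ctmc_step(s, R, 0.01)
  expect_equal(s, c(0.25, 0.75), tolerance = 1e-6)
  expect_error(generic_ctmc_step(c(1, 0, 0), R, 0.01), "dimension mismatch")
  expect_error(generic_ctmc_step(c(1, 0), R, 100), "negative")
})
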