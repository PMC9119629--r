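test_that("FVU and the combined cost evaluate as defined", {
  y <- c(1, 2, 3, 4)
  expect_equal(fvu(y, y), 0)
  expect_equal(fvu(y, c(1, 2, 3, 5)), 1 / 5)
  expect_equal(fvu_cost(y, c(1, 2, 3, 5), fit_config(alpha = 1, beta = 0)), 0.2)
  expect_equal(fvu_cost(y, rep(mean(y), 4), fit_config(alpha = 1, beta = 0)), 1)
  # log-term scale invariance: common positive rescaling leaves the cost
  f <- c(1.1, 1.9, 3.2, 3.9)
  cfg_log <- fit_config(alpha = 0, beta = 1)
  expect_equal(fvu_cost(y, f, cfg_log), fvu_cost(7 * y, 7 * f, cfg_log))
  expect_error(fvu_cost(c(1, -1, 2, 3), f, fit_config()), "positive")
  expect_error(fit_config(alpha = 0, beta = 0), "not both")
  expect_error(fvu(y, 1:3), "equal length")
  expect_error(fvu(rep(2, 4), y), "zero variance")
})

test_that("instantaneous time constant recovers exponential decays", {
  tt <- seq(0, 50, by = 0.1)
  r <- 1e-9 + 3 * exp(-tt / 7)
  tau <- instantaneous_tau(tt, r, 1e-9)$tau_ms
  expect_lt(max(abs(stats::na.omit(tau) - 7)) / 7, 0.01)
  # flat trace: every sample flagged undefined, none silently dropped
  flat <- instantaneous_tau(tt, rep(2, length(tt)), 2)
  expect_equal(nrow(flat), length(tt))
  expect_true(all(is.na(flat$tau_ms)))
  # two components with well-separated time constants plateau near each
  r2 <- 0.5 / 1 * exp(-tt / 1) + 0.5 / 100 * exp(-tt / 100)
  tau2 <- instantaneous_tau(tt, r2, 0)
  expect_lt(abs(tau2$tau_ms[tau2$time_ms == 0.5] - 1) / 1, 0.05)
  expect_lt(abs(tau2$tau_ms[tau2$time_ms == 45] - 100) / 100, 0.05)
  expect_error(instantaneous_tau(tt, r, 0, window = 4), "odd")
})

test_that("stimulus protocols enumerate the ramp-probe and paired-pulse cases", {
  ppf <- make_protocol("ppf")
  expect_length(ppf, 7L)
  expect_equal(vapply(ppf, function(x) x[2] - x[1], 0),
               c(2, 5, 10, 20, 50, 100, 200), ignore_attr = TRUE)
  rp <- make_protocol("ramp_probe")
  expect_equal(attr(rp, "n_raw"), 160L)
  expect_length(rp, 136L)
  expect_equal(rp[["ramp5_isi5_probe5"]], c(0, 5, 10, 15, 20, 25))
  expect_true(all(vapply(rp, function(x) all(diff(x) > 0), TRUE)))
  expect_false(anyDuplicated(names(rp)) > 0)
  # every case is a valid strictly increasing train
  for (tr in rp) validate_spike_train(tr)
  expect_error(make_protocol("ppf", probe_delays = -1), "positive")
})

test_that("profile fitting is idempotent at the truth", {
  m <- table2_release_model("synchronous")
  tt <- c(seq(0, 20, by = 0.1), seq(21, 200, by = 1))
  target <- eval_profile_filtered(m, tt)
  cfg <- fit_config(seed = 3, maxit = 200, restarts = 1)
  fit <- fit_profile(tt, target, m, free = c("P", "tau"), cfg = cfg)
  expect_lt(fit$cost, 1e-10)
  P0 <- vapply(m$components, `[[`, 0, "mass_P")
  P1 <- vapply(fit$model$components, `[[`, 0, "mass_P")
  expect_equal(P1, P0, tolerance = 1e-3)
})

test_that("profile fitting recovers perturbed parameters on a small model", {
  truth <- release_model(1e-6, list(
    release_component(0.02, 0.5, 2, 3, 0.2),
    release_component(0.01, 20, 1, 4, 0.5)
  ))
  tt <- c(seq(0, 15, by = 0.05), seq(15.5, 150, by = 0.5))
  target <- eval_profile_filtered(truth, tt)
  init <- truth
  for (i in 1:2) {
    init$components[[i]]$mass_P <- truth$components[[i]]$mass_P * 1.4
    init$components[[i]]$tau <- truth$components[[i]]$tau * 1.4
  }
  fit <- fit_profile(tt, target, init, free = c("P", "tau"),
                     cfg = fit_config(seed = 5, maxit = 2000, restarts = 2))
  expect_lt(fit$cost, 1e-6)
  for (i in 1:2) {
    expect_equal(fit$model$components[[i]]$mass_P,
                 truth$components[[i]]$mass_P, tolerance = 0.02)
    expect_equal(fit$model$components[[i]]$tau,
                 truth$components[[i]]$tau, tolerance = 0.02)
  }
})

test_that("noisy targets still yield usable mass estimates", {
  truth <- release_model(1e-6, list(release_component(0.02, 5, 1, 3, 0.3)))
  tt <- seq(0, 80, by = 0.2)
  clean <- eval_profile_filtered(truth, tt)
  errs <- vapply(1:5, function(rep) {
    set.seed(rep)
    noisy <- clean * exp(stats::rnorm(length(tt), 0, 0.01))
    fit <- fit_profile(tt, noisy, truth, free = "P",
                       cfg = fit_config(seed = rep, maxit = 500, restarts = 1))
    abs(fit$model$components[[1]]$mass_P / truth$components[[1]]$mass_P - 1)
  }, 0)
  expect_true(all(errs < 0.1))
})

test_that("facilitation metaparameter fitting handles structure and degeneracy", {
  trains <- make_protocol("ramp_probe")
  # constant masses: the non-facilitating limit is returned directly
  fit0 <- fit_facilitation_metaparams(rep(0.02, length(trains)), trains,
                                      0.02, list(facil_component(50, 5, 1)))
  expect_equal(fit0$comps[[1]]$n_steps, 1)
  expect_equal(fit0$comps[[1]]$xi, 0)
  expect_equal(fit0$comps[[1]]$limit_L, 1)
  # fewer cases than free metaparameters is rejected
  expect_error(
    fit_facilitation_metaparams(c(1, 2), trains[1:2], 1,
                                list(facil_component(50, 5, 1))),
    "fewer cases")
  # single-component recovery: time constant and limit from jittered start
  truth <- list(facil_component(126, 12.1, 1.67))
  masses <- vapply(trains, function(tr) {
    m <- apply_facilitation_to_train(list(truth), 0.0111, tr)
    m[length(tr), 1L]
  }, 0)
  init <- list(facil_component(126 * 1.5, 1 + 11.1 / 1.5, 1.67))
  fit <- fit_facilitation_metaparams(masses, trains, 0.0111, init,
                                     cfg = fit_config(seed = 17, maxit = 20000))
  expect_lt(fit$cost, 1e-8)
  expect_equal(fit$comps[[1]]$tau_f, 126, tolerance = 0.05)
  expect_equal(fit$comps[[1]]$limit_L, 64.31, tolerance = 0.05)
  # round trip: predictions from the fit match the source masses
  refit_masses <- vapply(trains, function(tr) {
    m <- apply_facilitation_to_train(list(fit$comps), 0.0111, tr)
    m[length(tr), 1L]
  }, 0)
  expect_lt(fvu(masses, refit_masses), 0.05)
})
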