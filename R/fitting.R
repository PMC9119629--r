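#' Fitting configuration
#'
#' @param alpha Weight of the linear-space fraction-of-variance-unexplained
#'   term (default 1).
#' @param beta Weight of the log-space term (default 1); `alpha` and `beta`
#'   must not both be zero.
#' @param maxit Iteration cap per simplex run.
#' @param restarts Number of jittered restarts (seeded; best run wins, ties
#'   broken by the earliest restart).
#' @param jitter_sd Log-space s.d. of the restart jitter.
#' @param seed Optional integer seed for the restart jitter.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(alpha = 1, beta = 1, maxit = 2000L, restarts = 3L,
                       jitter_sd = 0.1, seed = NULL) {
  if (alpha < 0 || beta < 0 || (alpha == 0 && beta == 0))
    stop("'alpha' and 'beta' must be >= 0 and not both 0")
  structure(list(alpha = alpha, beta = beta, maxit = as.integer(maxit),
                 restarts = as.integer(restarts), jitter_sd = jitter_sd,
                 seed = seed),
            class = "fit_config")
}

#' Fraction of variance unexplained
#'
#' `FVU(y, f) = sum((y - f)^2) / sum((y - mean(y))^2)`.
#'
#' @param y Observed values.
#' @param f Model values (same length).
#' @return The FVU (0 for a perfect fit; 1 for the constant mean).
#' @export
fvu <- function(y, f) {
  if (length(y) != length(f)) stop("'y' and 'f' must have equal length")
  denom <- sum((y - mean(y))^2)
  if (denom == 0) stop("'y' has zero variance; FVU undefined")
  sum((y - f)^2) / denom
}

#' Combined linear/log FVU cost
#'
#' `alpha * FVU(y, f) + beta * FVU(log y, log f)`.  The linear term is most
#' sensitive to the high-amplitude peaks; the log term to the slopes (time
#' constants) of the exponential components.
#'
#' @inheritParams fvu
#' @param cfg A [fit_config()].
#' @return The scalar cost.
#' @export
fvu_cost <- function(y, f, cfg = fit_config()) {
  stopifnot(inherits(cfg, "fit_config"))
  cost <- 0
  if (cfg$alpha > 0) cost <- cost + cfg$alpha * fvu(y, f)
  if (cfg$beta > 0) {
    if (any(y <= 0) || any(f <= 0))
      stop("log-FVU term requires strictly positive traces")
    cost <- cost + cfg$beta * fvu(log(y), log(f))
  }
  cost
}

#' Instantaneous decay time constant of a release-rate trace
#'
#' `tau(t) = -1 / (d/dt log(r(t) - baseline))`, the negative reciprocal
#' slope of the log excess rate, estimated with a smoothed least-squares
#' central difference over `window` points (default 5) on the uniform grid.
#' Samples where the excess rate is non-positive (or inside the stencil of
#' such a sample) are flagged `NA`, not dropped.
#'
#' @param time Uniform sample times, ms.
#' @param rate Release rates, 1/ms.
#' @param baseline The pre-stimulus rate `r(0)` subtracted before taking the
#'   logarithm.
#' @param window Odd stencil width (>= 3) of the least-squares derivative.
#' @return Data frame with columns `time_ms` and `tau_ms` (`NA` where
#'   undefined).
#' @export
instantaneous_tau <- function(time, rate, baseline, window = 5L) {
  if (length(time) != length(rate)) stop("'time' and 'rate' lengths differ")
  if (window < 3L || window %% 2L == 0L) stop("'window' must be odd and >= 3")
  h <- diff(time)
  if (any(abs(h - h[1L]) > 1e-9 * max(abs(h)))) stop("'time' must be uniform")
  h <- h[1L]
  ex <- rate - baseline
  lg <- ifelse(ex > 0, log(ex), NA_real_)
  half <- (window - 1L) %/% 2L
  offs <- -half:half
  wts <- offs / (sum(offs^2) * h)        # least-squares linear slope stencil
  n <- length(lg)
  slope <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- i + offs
    if (idx[1L] < 1L || idx[length(idx)] > n) next
    v <- lg[idx]
    if (anyNA(v)) next
    slope[i] <- sum(wts * v)
  }
  tau <- ifelse(is.na(slope) | slope == 0, NA_real_, -1 / slope)
  data.frame(time_ms = time, tau_ms = tau)
}

# Nelder-Mead in log-parameter space with seeded jittered restarts.
# fn takes the natural-scale parameter vector.
.simplex_log <- function(par0, fn, cfg) {
  obj <- function(lp) fn(exp(lp))
  lp0 <- log(par0)
  opt1 <- function(start) {
    if (length(start) == 1L)
      stats::optim(start, obj, method = "Brent", lower = start - 12,
                   upper = start + 12, control = list(maxit = cfg$maxit))
    else
      stats::optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = cfg$maxit, reltol = 1e-12))
  }
  runs <- vector("list", max(1L, cfg$restarts))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  for (r in seq_along(runs)) {
    start <- if (r == 1L) lp0 else lp0 + stats::rnorm(length(lp0), 0, cfg$jitter_sd)
    runs[[r]] <- opt1(start)
  }
  costs <- vapply(runs, `[[`, 0, "value")
  best <- runs[[which.min(costs)]]       # ties: which.min takes the earliest
  best <- opt1(best$par)                 # polish the winner once
  list(par = exp(best$par), value = best$value,
       converged = best$convergence == 0L)
}

#' Fit release-profile parameters to a target rate trace
#'
#' Minimizes [fvu_cost()] between the target trace and the filtered
#' single-spike profile ([eval_profile_filtered()]) over the chosen free
#' parameters by the Nelder-Mead simplex in log-parameter space (which keeps
#' all parameters positive), with seeded jittered restarts against local
#' minima.  Parameters not in `free` are held at their `init` values.
#'
#' @param time Target sample times, ms (spike at t = 0).
#' @param rate Target release rates, 1/ms (strictly positive when the log
#'   cost term is active).
#' @param init A [release_model()] giving initial values and the model
#'   structure.
#' @param free Character subset of `c("P", "tau", "k", "mu", "sigma")`:
#'   which parameters vary (across all components).
#' @param cfg A [fit_config()].
#' @return A list with `model` (the fitted [release_model()]), `cost`, and
#'   `converged` (FALSE if the iteration cap was reached).
#' @export
fit_profile <- function(time, rate, init, free = c("P", "tau"),
                        cfg = fit_config()) {
  stopifnot(inherits(init, "release_model"))
  free <- match.arg(free, c("P", "tau", "k", "mu", "sigma"), several.ok = TRUE)
  slot <- c(P = "mass_P", tau = "tau", k = "filt_k", mu = "filt_mu",
            sigma = "filt_sigma")[free]
  ncomp <- length(init$components)
  par0 <- unlist(lapply(slot, function(s)
    vapply(init$components, `[[`, 0, s)))

  build <- function(par) {
    m <- init
    pm <- matrix(par, ncomp, length(slot))
    for (j in seq_along(slot))
      for (ci in seq_len(ncomp))
        m$components[[ci]][[slot[j]]] <- pm[ci, j]
    m
  }
  fn <- function(par) {
    f <- eval_profile_filtered(build(par), time)
    if (any(!is.finite(f)) || any(f <= 0)) return(1e6)
    fvu_cost(rate, f, cfg)
  }
  res <- .simplex_log(par0, fn, cfg)
  list(model = build(res$par), cost = res$value, converged = res$converged)
}

#' Fit facilitation metaparameters to per-case component masses
#'
#' Stage two of the two-stage procedure: given the fitted final-spike mass of
#' one release component for every spike train of a protocol, recover the
#' facilitation metaparameters by minimizing the fraction of variance of the
#' masses unexplained by the model's predictions
#' ([apply_facilitation_to_train()]).  The search runs in the space of the
#' logarithms of (`tau_f`, `n_steps`, `limit_L`) for each facilitation
#' component; `xi` is derived as `log(L) / log(N)`.  A component whose
#' masses are constant across cases is returned directly as non-facilitating
#' (`n_steps = 1`, `xi = 0`).
#'
#' @param masses Final-spike mass of the release component, one per train.
#' @param trains List of spike-time vectors (one per case).
#' @param baseline Baseline mass `P_c0`.
#' @param init List of [facil_component()]s: structure and starting values.
#' @param cfg A [fit_config()].
#' @return A list with `comps` (fitted [facil_component()]s), `cost`, and
#'   `converged`.
#' @export
fit_facilitation_metaparams <- function(masses, trains, baseline, init,
                                        cfg = fit_config()) {
  if (length(masses) != length(trains))
    stop("need exactly one mass per spike-train case")
  nfree <- 3L * length(init)
  if (length(trains) < nfree)
    stop("fewer cases than free metaparameters")
  if (stats::sd(masses) < 1e-12 * max(abs(masses))) {
    return(list(comps = list(facil_component(1, 1, 0)), cost = 0,
                converged = TRUE))
  }
  # ISI matrix with leading Inf padding: an update after an infinite interval
  # always resets f to 1 regardless of history, so padded and unpadded trains
  # predict identical final-spike factors, and all cases vectorize together
  max_len <- max(vapply(trains, length, 0L))
  isi_mat <- t(vapply(trains, function(tr) {
    isi <- c(Inf, diff(tr))
    c(rep(Inf, max_len - length(isi)), isi)
  }, numeric(max_len)))
  predict_masses <- function(comps) {
    Fc <- 1
    for (fc in comps) {
      f <- numeric(nrow(isi_mat))
      decay <- exp(-isi_mat / fc$tau_f)
      for (j in seq_len(ncol(isi_mat))) {
        d <- f * decay[, j]
        f <- d + 1 - (d / fc$n_steps)^fc$n_steps
      }
      Fc <- Fc * f^fc$xi
    }
    baseline * Fc
  }
  par0 <- unlist(lapply(init, function(fc)
    c(fc$tau_f, max(fc$n_steps - 1, 1e-3), fc$limit_L)))
  build <- function(par) {
    pm <- matrix(par, 3L)
    lapply(seq_along(init), function(i) {
      N <- 1 + pm[2L, i]
      L <- pm[3L, i]
      facil_component(pm[1L, i], N, log(L) / log(N))
    })
  }
  fn <- function(par) {
    comps <- tryCatch(build(par), error = function(e) NULL)
    if (is.null(comps)) return(1e6)
    pred <- predict_masses(comps)
    if (any(!is.finite(pred)) || any(pred <= 0)) return(1e6)
    fvu_cost(masses, pred, cfg)
  }
  res <- .simplex_log(par0, fn, cfg)
  list(comps = build(res$par), cost = res$value, converged = res$converged)
}

#' Stimulus protocols for probing facilitation
#'
#' `"ppf"`: paired pulses (spike at 0 plus a probe) at each probe delay.
#' `"ramp_probe"`: every combination of ramp length (1-5 spikes), ramp ISI
#' (2, 5, 10, 20 ms) and probe delay (2, 5, 10, 20, 50, 100, 200 ms or no
#' probe), de-duplicated: one-spike ramps are ISI-independent, so the 160
#' raw cases reduce to 136 unique spike trains.
#'
#' @param kind `"ppf"` or `"ramp_probe"`.
#' @param ramp_counts Spikes in the ramp phase.
#' @param ramp_isis Ramp interspike intervals, ms.
#' @param probe_delays Probe delays after the last ramp spike, ms.
#' @return Named list of spike-time vectors
#'   (`ramp{n}_isi{ms}_probe{ms|none}`), with the raw (pre-deduplication)
#'   case count in attribute `"n_raw"`.
#' @export
make_protocol <- function(kind = c("ramp_probe", "ppf"),
                          ramp_counts = 1:5,
                          ramp_isis = c(2, 5, 10, 20),
                          probe_delays = c(2, 5, 10, 20, 50, 100, 200)) {
  kind <- match.arg(kind)
  if (any(ramp_counts < 1) || any(ramp_isis <= 0) || any(probe_delays <= 0))
    stop("protocol values must be positive")
  trains <- list()
  if (kind == "ppf") {
    for (d in probe_delays)
      trains[[sprintf("ppf_isi%g", d)]] <- c(0, d)
    attr(trains, "n_raw") <- length(probe_delays)
    return(trains)
  }
  # one-spike ramps are ISI-independent, so they are generated for the first
  # ISI only; coincidences between an n-spike ramp probed at its own ISI and
  # an (n+1)-spike ramp without probe are counted as distinct cases, matching
  # the protocol's 5 x 4 x (7 + 1) = 160 raw / 136 unique accounting
  n_raw <- 0L
  for (nr in ramp_counts) {
    for (isi in ramp_isis) {
      ramp <- (seq_len(nr) - 1L) * isi
      for (p in c(probe_delays, NA)) {
        n_raw <- n_raw + 1L
        if (nr == 1L && isi != ramp_isis[1L]) next
        tr <- if (is.na(p)) ramp else c(ramp, ramp[length(ramp)] + p)
        nm <- sprintf("ramp%d_isi%g_probe%s", nr, isi,
                      if (is.na(p)) "none" else format(p))
        trains[[nm]] <- tr
      }
    }
  }
  attr(trains, "n_raw") <- n_raw
  trains
}
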