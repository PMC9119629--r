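#' One exponential component of a release-rate profile
#'
#' A component contributes `(P/tau) exp(-t/tau) u(t)` to the spike-evoked
#' release rate, smeared in onset time by an ex-Gaussian delay filter with
#' exponential rate `filt_k`, Gaussian mean `filt_mu` and s.d. `filt_sigma`.
#' `mass_P` is the expected number of releases contributed by the component
#' per spike (a conditional-rate integral, so it may exceed one).
#'
#' @param mass_P Expected releases per spike (>= 0).
#' @param tau Decay constant, ms (> 0).
#' @param filt_k Delay-filter exponential rate, 1/ms (> 0).
#' @param filt_mu Delay-filter Gaussian mean, ms.
#' @param filt_sigma Delay-filter Gaussian s.d., ms (>= 0).
#' @return An object of class `release_component`.
#' @export
release_component <- function(mass_P, tau, filt_k, filt_mu = 0, filt_sigma = 0) {
  if (mass_P < 0) stop("'mass_P' must be >= 0")
  if (tau <= 0) stop("'tau' must be positive")
  if (filt_k <= 0) stop("'filt_k' must be positive")
  if (filt_sigma < 0) stop("'filt_sigma' must be >= 0")
  structure(list(mass_P = mass_P, tau = tau, filt_k = filt_k,
                 filt_mu = filt_mu, filt_sigma = filt_sigma),
            class = "release_component")
}

#' Multi-exponential release-rate model
#'
#' Spontaneous rate `r0` plus an ordered list of [release_component()]s;
#' the single-spike profile is
#' `r(t) = r0 + sum_c (P_c/tau_c) exp(-t/tau_c) u(t)` (optionally convolved
#' with each component's onset-delay filter).
#'
#' @param r0 Spontaneous release rate, 1/ms (>= 0).
#' @param components List of [release_component()] objects (length >= 1).
#' @param mechanism Label: `"synchronous"` or `"asynchronous"`.
#' @return An object of class `release_model`.
#' @export
release_model <- function(r0, components, mechanism = c("synchronous", "asynchronous")) {
  mechanism <- match.arg(mechanism)
  if (r0 < 0) stop("'r0' must be >= 0")
  if (!length(components)) stop("need at least one release component")
  if (!all(vapply(components, inherits, TRUE, "release_component")))
    stop("'components' must be release_component objects")
  structure(list(r0 = r0, components = components, mechanism = mechanism),
            class = "release_model")
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf("<release_model %s: r0=%g /ms, %d components>\n",
              x$mechanism, x$r0, length(x$components)))
  comp <- do.call(rbind, lapply(x$components, function(cc)
    data.frame(P = cc$mass_P, tau_ms = cc$tau, k_per_ms = cc$filt_k,
               mu_ms = cc$filt_mu, sigma_ms = cc$filt_sigma)))
  print(comp, row.names = TRUE)
  invisible(x)
}

#' Fitted single-spike release models at 400 nm from a 100-channel cluster
#'
#' The shipped parameter sets for the synchronous (4 components,
#' r0 = 5.70e-9 /ms) and asynchronous (3 components, r0 = 1.84e-5 /ms)
#' mechanisms, valid for sensors 400 nm from a cluster of 100
#' voltage-dependent calcium channels after a period of low activity.
#'
#' @param mechanism `"synchronous"` or `"asynchronous"`.
#' @return A [release_model()].
#' @export
table2_release_model <- function(mechanism = c("synchronous", "asynchronous")) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "synchronous") {
    release_model(5.70e-9, list(
      S1 = release_component(0.0175,   0.163, 1.79,  3.41, 0.168),
      S2 = release_component(0.0220,   6.50,  18.0,  3.56, 0.0977),
      S3 = release_component(1.70e-5,  80.0,  0.526, 10.0, 4.44),
      S4 = release_component(1.10e-5,  1000,  0.142, 50.0, 11.5)
    ), "synchronous")
  } else {
    release_model(1.84e-5, list(
      A1 = release_component(3.72e-3, 17.7,  1.60,   3.05, 0.243),
      A2 = release_component(0.0111,  76.9,  0.0759, 4.00, 1.14),
      A3 = release_component(0.0136,  1000,  0.0337, 76.5, 21.9)
    ), "asynchronous")
  }
}

# log of E(t; lam) = exp(-lam (t-mu) + lam^2 sigma^2 / 2) *
#                    Phi((t - mu - lam sigma^2) / sigma),
# the exponentially damped Gaussian integral underlying both the ex-Gaussian
# density (a = k E(t; k)) and the filtered profile.  E <= 1 for all t, so
# exponentiation never overflows; all terms are combined in log space.
.log_E <- function(t, lam, mu, sigma) {
  if (sigma == 0) {
    out <- -lam * (t - mu)
    out[t < mu] <- -Inf
    return(out)
  }
  -lam * (t - mu) + 0.5 * lam^2 * sigma^2 +
    stats::pnorm((t - mu - lam * sigma^2) / sigma, log.p = TRUE)
}

#' Ex-Gaussian probability density
#'
#' Density of the sum of an exponential (rate `k`) and a normal
#' (`mu`, `sigma`) random variable, evaluated in log space for numerical
#' stability at large `k * sigma`.  With `sigma = 0` it reduces pointwise to
#' the shifted exponential `k exp(-k (t - mu)) u(t - mu)`.
#'
#' @param t Evaluation times, ms.
#' @param k Exponential rate, 1/ms (> 0).
#' @param mu Gaussian mean, ms.
#' @param sigma Gaussian s.d., ms (>= 0).
#' @return Density values, 1/ms.
#' @export
ex_gaussian_pdf <- function(t, k, mu, sigma) {
  if (k <= 0) stop("'k' must be positive")
  if (sigma < 0) stop("'sigma' must be >= 0")
  exp(log(k) + .log_E(t, k, mu, sigma))
}

#' Cumulative distribution of the onset-delay filter
#'
#' `D(t) = Phi((t-mu)/sigma) - exp(-k(t - mu - k sigma^2/2)) *
#' Phi((t - mu - k sigma^2)/sigma)`; monotone nondecreasing from 0 to 1.
#' With `sigma = 0` it reduces exactly to
#' `(1 - exp(-k (t - mu))) u(t - mu)`.
#'
#' @inheritParams ex_gaussian_pdf
#' @return Probabilities in `[0, 1]`.
#' @export
arrival_delay_cdf <- function(t, k, mu, sigma) {
  if (k <= 0) stop("'k' must be positive")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) {
    out <- (1 - exp(-k * (t - mu)))
    out[t < mu] <- 0
    return(out)
  }
  out <- stats::pnorm((t - mu) / sigma) - exp(.log_E(t, k, mu, sigma))
  pmin(pmax(out, 0), 1)
}

# Unit-mass filtered component density: the convolution of the normalized
# exponential decay (1/tau) exp(-t/tau) u(t) with the ex-Gaussian filter.
# Closed form (difference of two damped-Gaussian terms):
#   g(t) = (k / (k tau - 1)) * (E(t; 1/tau) - E(t; k)),
# with the Erlang-Gaussian limit when |k - 1/tau| < 1e-9 / ms.
.filtered_density <- function(t, tau, k, mu, sigma) {
  lam <- 1 / tau
  if (abs(k - lam) >= 1e-9) {
    (k / (k * tau - 1)) * tau * lam * (exp(.log_E(t, lam, mu, sigma)) -
                                         exp(.log_E(t, k, mu, sigma)))
  } else if (sigma > 0) {
    z <- (t - mu - k * sigma^2) / sigma
    base <- exp(-k * (t - mu) + 0.5 * k^2 * sigma^2)
    k^2 * base * ((t - mu - k * sigma^2) * stats::pnorm(z) +
                    sigma * stats::dnorm(z))
  } else {
    out <- k^2 * (t - mu) * exp(-k * (t - mu))
    out[t < mu] <- 0
    out
  }
}

#' Evaluate the unfiltered single-spike release profile
#'
#' `r(t) = r0 + sum_c (P_c / tau_c) exp(-t / tau_c) u(t)`, with `t` measured
#' from the calcium arrival time.  Integrating any component over t >= 0
#' recovers its mass `P_c`.
#'
#' @param model A [release_model()].
#' @param t Evaluation times, ms.
#' @return Release rates, 1/ms.
#' @export
eval_profile_unfiltered <- function(model, t) {
  stopifnot(inherits(model, "release_model"))
  r <- rep(model$r0, length(t))
  pos <- t >= 0
  for (cc in model$components)
    r[pos] <- r[pos] + cc$mass_P / cc$tau * exp(-t[pos] / cc$tau)
  r
}

#' Evaluate the filtered single-spike release profile
#'
#' Each component's exponential decay is convolved with its ex-Gaussian
#' onset-delay filter (closed form); the filter integrates to one, so it
#' shifts release in time without changing each component's mass `P_c`.
#'
#' @inheritParams eval_profile_unfiltered
#' @param spike_at Spike time, ms (profile is shifted by this amount).
#' @return Release rates, 1/ms.
#' @export
eval_profile_filtered <- function(model, t, spike_at = 0) {
  stopifnot(inherits(model, "release_model"))
  r <- rep(model$r0, length(t))
  for (cc in model$components)
    r <- r + cc$mass_P * .filtered_density(t - spike_at, cc$tau, cc$filt_k,
                                           cc$filt_mu, cc$filt_sigma)
  r
}

#' Validate a spike train
#'
#' @param spikes Numeric spike times, ms.
#' @return The spike times, invisibly, after checking they are finite and
#'   strictly increasing with no duplicates.
#' @export
validate_spike_train <- function(spikes) {
  spikes <- as.numeric(spikes)
  if (any(!is.finite(spikes))) stop("spike times must be finite")
  if (length(spikes) > 1L && any(diff(spikes) <= 0))
    stop("spike times must be strictly increasing (no duplicates)")
  invisible(spikes)
}

#' Combine release profiles across a spike train
#'
#' In `"expected"` mode each spike's filtered component response is cut short
#' by every later spike through the factor `(1 - D_c(t - t_sj))`, where `D_c`
#' is that component's onset-delay CDF ([arrival_delay_cdf()]): the expected
#' profile over the ensemble of random calcium arrival times.  In
#' `"fixed_arrivals"` mode the supplied per-spike, per-component calcium
#' arrival times switch the unfiltered profiles with hard Heaviside steps
#' (truncation applied in arrival-time order).  The spontaneous rate `r0`
#' is added exactly once.
#'
#' @param model A [release_model()].
#' @param spikes Strictly increasing spike times, ms.
#' @param t Evaluation times, ms.
#' @param per_spike_masses Optional matrix (`length(spikes)` rows, one column
#'   per component) of facilitated masses `P_c(n)`; default: baseline masses
#'   for every spike.
#' @param mode `"expected"` or `"fixed_arrivals"`.
#' @param arrivals Matrix of calcium arrival times (same shape as
#'   `per_spike_masses`); required in `"fixed_arrivals"` mode.
#' @return Release rates at `t`, 1/ms.
#' @export
multi_spike_profile <- function(model, spikes, t, per_spike_masses = NULL,
                                mode = c("expected", "fixed_arrivals"),
                                arrivals = NULL) {
  stopifnot(inherits(model, "release_model"))
  mode <- match.arg(mode)
  spikes <- as.numeric(spikes)
  validate_spike_train(spikes)
  ncomp <- length(model$components)
  nspk <- length(spikes)
  if (is.null(per_spike_masses)) {
    per_spike_masses <- matrix(vapply(model$components, `[[`, 0, "mass_P"),
                               nspk, ncomp, byrow = TRUE)
  }
  per_spike_masses <- as.matrix(per_spike_masses)
  if (!all(dim(per_spike_masses) == c(nspk, ncomp)))
    stop("'per_spike_masses' must be spikes x components")

  r <- rep(model$r0, length(t))
  if (mode == "expected") {
    for (ci in seq_len(ncomp)) {
      cc <- model$components[[ci]]
      for (si in seq_len(nspk)) {
        contrib <- per_spike_masses[si, ci] *
          .filtered_density(t - spikes[si], cc$tau, cc$filt_k, cc$filt_mu,
                            cc$filt_sigma)
        for (sj in seq_len(nspk)) {
          if (spikes[sj] > spikes[si])
            contrib <- contrib * (1 - arrival_delay_cdf(t - spikes[sj],
                                                        cc$filt_k, cc$filt_mu,
                                                        cc$filt_sigma))
        }
        r <- r + contrib
      }
    }
  } else {
    if (is.null(arrivals)) stop("'arrivals' is required in fixed_arrivals mode")
    arrivals <- as.matrix(arrivals)
    if (!all(dim(arrivals) == c(nspk, ncomp)))
      stop("'arrivals' must be spikes x components")
    for (ci in seq_len(ncomp)) {
      cc <- model$components[[ci]]
      ord <- order(arrivals[, ci])
      a <- arrivals[ord, ci]
      m <- per_spike_masses[ord, ci]
      for (si in seq_len(nspk)) {
        contrib <- m[si] / cc$tau * exp(-(t - a[si]) / cc$tau) * (t >= a[si])
        if (si < nspk) contrib <- contrib * (t < a[si + 1L])
        r <- r + contrib
      }
    }
  }
  r
}
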