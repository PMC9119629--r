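#' Sample calcium arrival delays for one release component
#'
#' Each delay is the sum of a normal draw (`filt_mu`, `filt_sigma`) and an
#' exponential draw (rate `filt_k`): an ex-Gaussian sample.  Added to a spike
#' time, a delay gives the time at which that component starts responding to
#' the spike.
#'
#' @param comp A [release_component()].
#' @param n Number of delays to draw (>= 1).
#' @return Numeric vector of delays, ms.
#' @export
sample_arrival_delays <- function(comp, n) {
  stopifnot(inherits(comp, "release_component"), n >= 1)
  stats::rnorm(n, comp$filt_mu, comp$filt_sigma) + stats::rexp(n, comp$filt_k)
}

#' Sample release-event times for one trial
#'
#' Event-driven stochastic realization of a release model over a spike
#' train.  Per spike and component: draw a calcium arrival time (spike time
#' plus ex-Gaussian delay), a Poisson event count with mean equal to the
#' (facilitated) component mass, and candidate event times as arrival plus
#' exponential waits with mean `tau`; candidates falling at or after the
#' component's next arrival are discarded (hard profile switching).
#' Spontaneous events form a homogeneous Poisson process at rate `r0`
#' throughout `[0, duration]`.  In `"single_vesicle"` mode only the first
#' event is kept; with `refractory = TRUE` eligibility resumes after an
#' exponential recovery delay with mean `refractory_eps`.
#'
#' @param model A [release_model()].
#' @param spikes Strictly increasing spike times, ms (may be empty).
#' @param duration Simulation window, ms (must cover the spikes).
#' @param facil Optional facilitation parameters as in
#'   [apply_facilitation_to_train()]; if `NULL` baseline masses are used
#'   with a warning.
#' @param mode `"poisson"` (time-varying Poisson process, default) or
#'   `"single_vesicle"` (hazard reading: at most one event per recovery
#'   period).
#' @param refractory Logical; in single-vesicle mode, resample eligibility
#'   after an exponential recovery interval (mean `refractory_eps` ms).
#' @param refractory_eps Recovery time constant, ms (default 6.34).
#' @param quiet Suppress the missing-facilitation warning.
#' @return A data frame with columns `time_ms`, `mechanism`, `component`
#'   (0 for spontaneous events) and `spike_index` (NA for spontaneous).
#' @export
sample_release_events <- function(model, spikes, duration, facil = NULL,
                                  mode = c("poisson", "single_vesicle"),
                                  refractory = FALSE, refractory_eps = 6.34,
                                  quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "release_model"))
  spikes <- as.numeric(spikes)
  validate_spike_train(spikes)
  if (length(spikes) && max(spikes) > duration)
    stop("'duration' must cover the spike train")
  ncomp <- length(model$components)
  nspk <- length(spikes)
  base <- vapply(model$components, `[[`, 0, "mass_P")
  if (nspk > 0L) {
    if (is.null(facil)) {
      if (!quiet)
        warning("no facilitation parameters supplied; using baseline masses")
      masses <- matrix(base, nspk, ncomp, byrow = TRUE)
    } else {
      masses <- apply_facilitation_to_train(facil, base, spikes)
    }
  }

  times <- numeric(0); comp_id <- integer(0); spk_id <- integer(0)
  if (nspk > 0L) {
    for (ci in seq_len(ncomp)) {
      cc <- model$components[[ci]]
      arr <- spikes + sample_arrival_delays(cc, nspk)
      ord <- order(arr)
      nxt <- c(arr[ord][-1L], Inf)            # next arrival in arrival order
      for (oi in seq_len(nspk)) {
        si <- ord[oi]
        nev <- stats::rpois(1L, masses[si, ci])
        if (nev == 0L) next
        tt <- arr[si] + stats::rexp(nev, 1 / cc$tau)
        tt <- tt[tt < nxt[oi] & tt <= duration]
        if (length(tt)) {
          times <- c(times, tt)
          comp_id <- c(comp_id, rep.int(ci, length(tt)))
          spk_id <- c(spk_id, rep.int(si, length(tt)))
        }
      }
    }
  }
  n_sp <- stats::rpois(1L, model$r0 * duration)
  if (n_sp > 0L) {
    times <- c(times, stats::runif(n_sp, 0, duration))
    comp_id <- c(comp_id, rep.int(0L, n_sp))
    spk_id <- c(spk_id, rep.int(NA_integer_, n_sp))
  }

  mech <- ifelse(comp_id == 0L, "spontaneous", model$mechanism)
  ev <- data.frame(time_ms = times, mechanism = mech, component = comp_id,
                   spike_index = spk_id, stringsAsFactors = FALSE)
  ev <- ev[order(ev$time_ms), , drop = FALSE]
  rownames(ev) <- NULL

  if (mode == "single_vesicle" && nrow(ev) > 0L) {
    keep <- logical(nrow(ev))
    eligible_from <- -Inf
    for (i in seq_len(nrow(ev))) {
      if (ev$time_ms[i] >= eligible_from) {
        keep[i] <- TRUE
        if (!refractory) break
        eligible_from <- ev$time_ms[i] + stats::rexp(1L, 1 / refractory_eps)
      }
    }
    ev <- ev[keep, , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

#' Sample an ensemble of release trials (vectorized)
#'
#' Draws `n_trials` independent realizations of [sample_release_events()]'s
#' `"poisson"` mode in vectorized form, for histogram-level validation
#' against the analytic profile.  Within each trial, all events of a
#' component triggered by one spike share that trial's arrival-delay draw,
#' and truncation by the component's next arrival is applied per trial.
#'
#' @inheritParams sample_release_events
#' @param n_trials Number of independent trials.
#' @return A data frame with columns `trial`, `time_ms`, `component`,
#'   `spike_index` (NA for spontaneous events, component 0).
#' @export
sample_release_ensemble <- function(model, spikes, duration, n_trials,
                                    facil = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "release_model"), n_trials >= 1)
  spikes <- as.numeric(spikes)
  validate_spike_train(spikes)
  ncomp <- length(model$components)
  nspk <- length(spikes)
  base <- vapply(model$components, `[[`, 0, "mass_P")
  if (nspk > 0L) {
    if (is.null(facil)) {
      if (!quiet)
        warning("no facilitation parameters supplied; using baseline masses")
      masses <- matrix(base, nspk, ncomp, byrow = TRUE)
    } else {
      masses <- apply_facilitation_to_train(facil, base, spikes)
    }
  }

  out <- vector("list", ncomp + 1L)
  for (ci in seq_len(ncomp)) {
    if (nspk == 0L) break
    cc <- model$components[[ci]]
    # arrivals: n_trials x nspk
    arr <- matrix(rep(spikes, each = n_trials), n_trials, nspk) +
      matrix(sample_arrival_delays(cc, n_trials * nspk), n_trials, nspk)
    # next arrival (per trial) strictly after each spike's arrival
    nxt <- matrix(Inf, n_trials, nspk)
    if (nspk > 1L) {
      for (j in seq_len(nspk)) {
        for (k in seq_len(nspk)) {
          if (k == j) next
          cand <- ifelse(arr[, k] > arr[, j], arr[, k], Inf)
          nxt[, j] <- pmin(nxt[, j], cand)
        }
      }
    }
    for (si in seq_len(nspk)) {
      counts <- stats::rpois(n_trials, masses[si, ci])
      tot <- sum(counts)
      if (tot == 0L) next
      trial <- rep.int(seq_len(n_trials), counts)
      tt <- arr[trial, si] + stats::rexp(tot, 1 / cc$tau)
      ok <- tt < nxt[trial, si] & tt <= duration
      if (any(ok))
        out[[ci]] <- rbind(out[[ci]],
                           data.frame(trial = trial[ok], time_ms = tt[ok],
                                      component = ci, spike_index = si))
    }
  }
  n_sp <- stats::rpois(n_trials, model$r0 * duration)
  tot <- sum(n_sp)
  if (tot > 0L) {
    out[[ncomp + 1L]] <- data.frame(trial = rep.int(seq_len(n_trials), n_sp),
                                    time_ms = stats::runif(tot, 0, duration),
                                    component = 0L, spike_index = NA_integer_)
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ev))
    ev <- data.frame(trial = integer(0), time_ms = numeric(0),
                     component = integer(0), spike_index = integer(0))
  ev <- ev[order(ev$trial, ev$time_ms), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
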