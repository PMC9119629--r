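#' Uniformly sampled calcium concentration trace
#'
#' Container for free intracellular calcium concentration on a uniform time
#' grid: `value[i]` is the concentration at `t0 + (i-1) * dt`.
#'
#' @param values Concentrations, uM (all >= 0).
#' @param dt Grid spacing, ms (> 0).
#' @param t0 Time of the first sample, ms.
#' @param baseline Resting concentration, uM (default: the first value).
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(values, dt, t0 = 0, baseline = values[1L]) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a trace needs at least one sample")
  if (any(!is.finite(values)) || any(values < 0))
    stop("trace values must be finite and non-negative")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  structure(list(values = values, dt = dt, t0 = t0, baseline = baseline),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace: %d samples, dt=%g ms, t=[%g, %g] ms, baseline=%g uM>\n",
              length(x$values), x$dt, x$t0,
              x$t0 + (length(x$values) - 1L) * x$dt, x$baseline))
  invisible(x)
}

#' Time grid of a calcium trace
#' @param trace A [ca_trace()] object.
#' @return Numeric vector of sample times, ms.
#' @export
ca_trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1L) * trace$dt
}

#' Specification of a spike-evoked calcium transient
#'
#' Phenomenological stand-in for the averaged calcium transient seen by a
#' sensor at a given distance from the channel cluster: a sum of exponential
#' decay components whose common amplitude scale drops off exponentially with
#' distance (length constant 0.204 um), superposed linearly across spikes on
#' a constant baseline (default 100 nM).
#'
#' @param components Two-column matrix or data frame (`amplitude` uM,
#'   `tau` ms), one row per decay component.
#' @param baseline Resting concentration, uM (default 0.1).
#' @param onset_delay Delay from spike time to transient onset, ms.  Absorbs
#'   the convention that spike times mark the pre-rising-phase point of the
#'   action potential waveform.
#' @param distance Sensor distance from the channel cluster, um.
#' @param length_constant Exponential length constant of the amplitude
#'   drop-off, um (default 0.204).
#' @return An object of class `ca_transient_spec`.
#' @export
ca_transient_spec <- function(components = cbind(amplitude = c(2.0, 0.08, 0.015),
                                                 tau = c(1.5, 20, 1000)),
                              baseline = 0.1, onset_delay = 1.0,
                              distance = 0, length_constant = 0.204) {
  components <- as.matrix(components)
  if (ncol(components) != 2L) stop("'components' needs amplitude and tau columns")
  colnames(components) <- c("amplitude", "tau")
  if (any(components[, "amplitude"] < 0)) stop("amplitudes must be >= 0")
  if (any(components[, "tau"] <= 0)) stop("decay constants must be positive")
  if (baseline < 0) stop("'baseline' must be >= 0")
  if (length_constant <= 0) stop("'length_constant' must be positive")
  structure(list(components = components, baseline = baseline,
                 onset_delay = onset_delay, distance = distance,
                 length_constant = length_constant),
            class = "ca_transient_spec")
}

#' Synthesize a calcium trace for a spike train
#'
#' Evaluates `baseline + sum over spikes and components of
#' A_j exp(-distance/length_constant) exp(-(t - t_s - onset_delay)/tau_j)` for
#' `t >= t_s + onset_delay`; transients superpose linearly across spikes
#' (no buffer saturation), so the trace never undershoots the baseline.
#'
#' @param spec A [ca_transient_spec()].
#' @param spikes Sorted spike times, ms (may be empty).
#' @param duration Trace duration, ms.
#' @param dt Grid spacing, ms (default 0.1).
#' @param t0 Start time of the trace, ms.
#' @return A [ca_trace()].
#' @export
synth_ca_trace <- function(spec, spikes, duration, dt = 0.1, t0 = 0) {
  stopifnot(inherits(spec, "ca_transient_spec"))
  if (dt <= 0) stop("'dt' must be positive")
  spikes <- as.numeric(spikes)
  if (is.unsorted(spikes, strictly = FALSE)) stop("'spikes' must be sorted ascending")
  if (length(spikes) && max(spikes) > t0 + duration)
    stop("'duration' must cover all spikes")
  tt <- seq(t0, t0 + duration, by = dt)
  v <- rep(spec$baseline, length(tt))
  scale <- exp(-spec$distance / spec$length_constant)
  for (ts in spikes) {
    rel <- tt - ts - spec$onset_delay
    on <- rel >= 0
    if (!any(on)) next
    for (j in seq_len(nrow(spec$components))) {
      A <- spec$components[j, "amplitude"] * scale
      tau <- spec$components[j, "tau"]
      v[on] <- v[on] + A * exp(-rel[on] / tau)
    }
  }
  ca_trace(v, dt = dt, t0 = t0, baseline = spec$baseline)
}

#' Single-sample calcium impulse on a constant background
#'
#' Constant concentration `ca0` everywhere except one grid sample at
#' `t_impulse`, elevated by `impulse_amplitude`.  Used to probe the
#' impulse-response of the release machinery: driving the synchronous sensor
#' with `ca0 = 0` yields a conditional release rate that decays with a single
#' exponential component.
#'
#' @param ca0 Background concentration, uM.
#' @param impulse_amplitude Added concentration at the impulse sample, uM.
#' @param t_impulse Impulse time, ms (snapped to the nearest grid sample).
#' @param duration Trace duration, ms.
#' @param dt Grid spacing, ms.
#' @param t0 Start time, ms.
#' @return A [ca_trace()].
#' @export
ca_impulse_trace <- function(ca0, impulse_amplitude, t_impulse, duration,
                             dt = 0.1, t0 = 0) {
  if (impulse_amplitude < 0) stop("'impulse_amplitude' must be >= 0")
  if (t_impulse < t0 || t_impulse > t0 + duration)
    stop("'t_impulse' must lie inside the trace window")
  tt <- seq(t0, t0 + duration, by = dt)
  v <- rep(ca0, length(tt))
  i <- which.min(abs(tt - t_impulse))
  v[i] <- v[i] + impulse_amplitude
  ca_trace(v, dt = dt, t0 = t0, baseline = ca0)
}
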