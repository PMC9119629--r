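#' One linear facilitation component
#'
#' A release component's facilitation factor is a product of saturating
#' linear factors `f_i` raised to nonlinearity exponents `xi_i`
#' ([facil_factor()]).  Each linear factor decays towards zero between
#' spikes with time constant `tau_f` and increments by (at most) one at each
#' spike; the saturating update caps it at `n_steps`, so its contribution to
#' the overall factor never exceeds `limit_L = n_steps ^ xi`.
#' `(n_steps = 1, xi = 0)` encodes a non-facilitating component
#' (`limit_L = 1`).
#'
#' @param tau_f Decay time constant, ms (> 0).
#' @param n_steps Number of linear steps to saturation, >= 1.
#' @param xi Nonlinearity exponent (dimensionless; >= 0 for facilitation,
#'   negative values are admitted to encode release-independent depression
#'   but are not validated here).
#' @return An object of class `facil_component` with derived field `limit_L`.
#' @export
facil_component <- function(tau_f, n_steps, xi) {
  if (tau_f <= 0) stop("'tau_f' must be positive")
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  structure(list(tau_f = tau_f, n_steps = n_steps, xi = xi,
                 limit_L = n_steps^xi),
            class = "facil_component")
}

#' Per-spike update of one linear facilitation factor
#'
#' Decay-then-increment update applied at each spike (including the first,
#' for which `delta_t = Inf` encodes infinite preceding rest).  With
#' `mode = "saturating"` (default)
#' `f <- d + 1 - (d / N)^N` where `d = f_prev * exp(-delta_t / tau_f)`,
#' which never exceeds `N = n_steps`; `mode = "unbounded"` uses `f <- d + 1`.
#'
#' @param f_prev Previous factor value (0 for the fully decayed state that
#'   precedes the first spike).
#' @param comp A [facil_component()].
#' @param delta_t Interspike interval, ms (> 0; `Inf` allowed).
#' @param mode `"saturating"` or `"unbounded"`.
#' @return The updated factor value.
#' @export
facil_update <- function(f_prev, comp, delta_t, mode = c("saturating", "unbounded")) {
  mode <- match.arg(mode)
  stopifnot(inherits(comp, "facil_component"))
  if (is.na(delta_t) || delta_t <= 0)
    stop("'delta_t' must be positive (coincident spikes are rejected upstream)")
  d <- f_prev * exp(-delta_t / comp$tau_f)
  if (mode == "unbounded") d + 1
  else d + 1 - (d / comp$n_steps)^comp$n_steps
}

#' Nonlinear combination of linear facilitation factors
#'
#' `F = prod_i f_i ^ xi_i`; with all factors between 1 (fully rested) and
#' their saturation values `n_steps_i`, `F` lies between 1 and
#' `prod_i limit_L_i`.
#'
#' @param f_values Current linear factors, one per component.
#' @param comps List of [facil_component()]s (same length).
#' @return The facilitation factor `F`.
#' @export
facil_factor <- function(f_values, comps) {
  if (length(f_values) != length(comps))
    stop("'f_values' and 'comps' must have the same length")
  prod(vapply(seq_along(comps), function(i) f_values[i]^comps[[i]]$xi, 0))
}

#' Facilitated component masses across a spike train
#'
#' Applies the per-spike facilitation updates to every release component and
#' returns the facilitated masses `P_c(n) = P_c0 * F_c(n)`.  All linear
#' factors start fully decayed (`f = 0`), so the first spike (or any spike
#' after a long rest) yields `f = 1`, `F = 1` and the baseline mass exactly:
#' every spike is treated the same way.
#'
#' @param facil_params List (one element per release component) of lists of
#'   [facil_component()]s; an empty inner list means no facilitation.
#' @param baselines Baseline masses `P_c0`, one per release component.
#' @param spikes Strictly increasing spike times, ms.
#' @param mode Passed to [facil_update()].
#' @return Matrix of masses, `length(spikes)` rows x components columns, with
#'   the facilitation factors in attribute `"factors"`.
#' @export
apply_facilitation_to_train <- function(facil_params, baselines, spikes,
                                        mode = "saturating") {
  spikes <- as.numeric(spikes)
  validate_spike_train(spikes)
  ncomp <- length(baselines)
  if (length(facil_params) != ncomp)
    stop("'facil_params' must have one entry per release component")
  nspk <- length(spikes)
  isi <- c(Inf, diff(spikes))
  fac <- matrix(1, nspk, ncomp)
  for (ci in seq_len(ncomp)) {
    comps <- facil_params[[ci]]
    if (!length(comps)) next
    f <- numeric(length(comps))    # fully decayed before the first spike
    for (si in seq_len(nspk)) {
      for (k in seq_along(comps))
        f[k] <- facil_update(f[k], comps[[k]], isi[si], mode = mode)
      fac[si, ci] <- facil_factor(f, comps)
    }
  }
  masses <- sweep(fac, 2L, baselines, `*`)
  attr(masses, "factors") <- fac
  masses
}

#' Facilitation metaparameters for the shipped release components
#'
#' The fitted facilitation components for each release component of the
#' 400-nm release models ([table2_release_model()]), keyed S1, S2, S3, S4,
#' A1, A2, A3.  The two fastest synchronous components and the fastest
#' asynchronous component carry two facilitation timescales each
#' (S11/S12, S21/S22, A11/A12); the slowest components (tau = 1000 ms) do
#' not facilitate (`n_steps = 1`, `xi = 0`).
#'
#' @param mechanism `"synchronous"` or `"asynchronous"`.
#' @return Named list (one entry per release component) of lists of
#'   [facil_component()]s.
#' @export
table3_facilitation <- function(mechanism = c("synchronous", "asynchronous")) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "synchronous") {
    list(
      S1 = list(facil_component(95.9, 7.00, 1.27),
                facil_component(7.66, 2.32, 2.93)),
      S2 = list(facil_component(13.1, 10.0, 1.23),
                facil_component(114,  17.6, 1.68)),
      S3 = list(facil_component(199,  12.5, 2.67)),
      S4 = list()
    )
  } else {
    list(
      A1 = list(facil_component(141,  12.2, 1.48),
                facil_component(17.2, 12.5, 0.996)),
      A2 = list(facil_component(126,  12.1, 1.67)),
      A3 = list()
    )
  }
}
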