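#' Calcium-sensor kinetic scheme
#'
#' Defines the Markov scheme of a calcium sensor mediating vesicle fusion: a
#' birth-death chain over the number of bound calcium ions (0..`n_sites`) with
#' cooperative unbinding and an absorbing fusion ("release") transition out of
#' the fully bound state.  Syt-1 (synchronous release) binds five ions; Syt-7
#' (asynchronous release) binds two.
#'
#' All rates use internal units of ms and uM: `k_on` in 1/(uM ms), `k_off` and
#' `gamma_fuse` in 1/ms.  Published second-order rates in 1/(M s) convert by
#' `1e-9` (e.g. 6.12e7 / (M s) = 0.0612 / (uM ms)); first-order rates in 1/s
#' convert by `1e-3`.
#'
#' @param n_sites Number of calcium binding sites (>= 1).
#' @param k_on Per-site binding rate constant, 1/(uM ms).
#' @param k_off Base unbinding rate constant, 1/ms.
#' @param coop_b Unbinding cooperativity factor, in (0, 1]; the n-th bound ion
#'   unbinds at rate `n * coop_b^(n-1) * k_off`.
#' @param gamma_fuse Fusion rate from the fully bound state, 1/ms.
#' @param refractory_eps Post-release refractory time constant, ms (only used
#'   by the event sampler's single-vesicle mode).
#' @param label Optional mechanism label, e.g. `"synchronous"`.
#' @return An object of class `sensor_kinetics`.
#' @seealso [syt1_kinetics()], [syt7_kinetics()] for the shipped parameter
#'   sets; [sensor_rate_matrix()], [quasi_stationary_rate()].
#' @export
sensor_kinetics <- function(n_sites, k_on, k_off, coop_b, gamma_fuse,
                            refractory_eps = 0, label = NULL) {
  stopifnot(length(n_sites) == 1L, length(k_on) == 1L, length(k_off) == 1L,
            length(coop_b) == 1L, length(gamma_fuse) == 1L)
  if (n_sites < 1 || n_sites != round(n_sites))
    stop("'n_sites' must be a positive integer")
  if (k_on <= 0 || k_off <= 0 || gamma_fuse <= 0)
    stop("'k_on', 'k_off' and 'gamma_fuse' must be positive")
  if (coop_b <= 0 || coop_b > 1)
    stop("'coop_b' must be in (0, 1]")
  if (refractory_eps < 0)
    stop("'refractory_eps' must be non-negative")
  structure(list(n_sites = as.integer(n_sites), k_on = k_on, k_off = k_off,
                 coop_b = coop_b, gamma_fuse = gamma_fuse,
                 refractory_eps = refractory_eps, label = label),
            class = "sensor_kinetics")
}

#' @export
print.sensor_kinetics <- function(x, ...) {
  cat(sprintf("<sensor_kinetics%s: %d sites, k_on=%g /(uM ms), k_off=%g /ms, b=%g, gamma=%g /ms>\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n_sites, x$k_on, x$k_off, x$coop_b, x$gamma_fuse))
  invisible(x)
}

#' Synchronous (Syt-1) sensor kinetics
#'
#' Five-site synchronous release sensor: k_on = 6.12e7 /(M s) = 0.0612
#' /(uM ms), k_off = 2.32e3 /s, b = 0.25, gamma = 6.0e3 /s, refractory
#' eps = 6.34 ms.
#'
#' @return A [sensor_kinetics()] object.
#' @export
syt1_kinetics <- function() {
  sensor_kinetics(5L, k_on = 0.0612, k_off = 2.32, coop_b = 0.25,
                  gamma_fuse = 6.0, refractory_eps = 6.34,
                  label = "synchronous")
}

#' Asynchronous (Syt-7) sensor kinetics
#'
#' Two-site asynchronous release sensor: k_on = 3.82e6 /(M s) = 0.00382
#' /(uM ms), k_off = 13 /s, b = 0.25, gamma = 50 /s.
#'
#' @return A [sensor_kinetics()] object.
#' @export
syt7_kinetics <- function() {
  sensor_kinetics(2L, k_on = 0.00382, k_off = 0.013, coop_b = 0.25,
                  gamma_fuse = 0.05, refractory_eps = 6.34,
                  label = "asynchronous")
}

#' Transition-rate matrix of a sensor at a given calcium concentration
#'
#' Builds the infinitesimal generator of the sensor chain at free calcium
#' concentration `ca`.  Convention: columns index the current state (0..N
#' bound ions), rows the next state, so that probabilities propagate as
#' `s(t + dt) = (I + dt * T) s(t)` (left multiplication).  The binding entry
#' (n -> n+1) is `(N - n) k_on ca`; the unbinding entry (n -> n-1) is
#' `n coop_b^(n-1) k_off`; diagonals carry minus the total exit rate, and the
#' fully bound diagonal additionally carries `-gamma_fuse` (fusion acts as a
#' killing transition out of the tracked chain).  Every column sums to zero
#' except the last, which sums to `-gamma_fuse`.
#'
#' @param kin A [sensor_kinetics()] object.
#' @param ca Free calcium concentration, uM (scalar, >= 0).
#' @return A `(n_sites+1) x (n_sites+1)` numeric matrix, units 1/ms.
#' @export
sensor_rate_matrix <- function(kin, ca) {
  stopifnot(inherits(kin, "sensor_kinetics"), length(ca) == 1L)
  if (is.na(ca) || ca < 0) stop("'ca' must be a non-negative concentration")
  N <- kin$n_sites
  m <- matrix(0, N + 1L, N + 1L)
  n <- 0:(N - 1L)                                  # states with binding out
  bind <- (N - n) * kin$k_on * ca
  unbind <- (n + 1L) * kin$coop_b^n * kin$k_off    # rate out of state n+1
  m[cbind(n + 2L, n + 1L)] <- bind
  m[cbind(n + 1L, n + 2L)] <- unbind
  diag(m) <- -(c(bind, 0) + c(0, unbind))
  m[N + 1L, N + 1L] <- m[N + 1L, N + 1L] - kin$gamma_fuse
  m
}

#' One explicit step of a generic continuous-time Markov chain
#'
#' Linear first-order propagation `s + dt * R s` without renormalization.
#' Supports user-supplied molecular species (e.g. voltage-dependent calcium
#' channels, calbindin buffer, PMCA pumps) whose rate constants come from
#' configuration; a conservative generator (columns summing to zero) leaves
#' the total probability mass unchanged.
#'
#' @param probs Numeric state-probability vector.
#' @param rate_matrix Square generator matrix (column = current state), 1/ms.
#' @param dt Time step, ms (>= 0); must be small enough that no entry of the
#'   result goes negative.
#' @return The propagated probability vector.
#' @export
generic_ctmc_step <- function(probs, rate_matrix, dt) {
  if (!is.matrix(rate_matrix) || nrow(rate_matrix) != ncol(rate_matrix))
    stop("'rate_matrix' must be a square matrix")
  if (length(probs) != ncol(rate_matrix))
    stop(sprintf("dimension mismatch: %d states vs %d x %d matrix",
                 length(probs), nrow(rate_matrix), ncol(rate_matrix)))
  if (dt < 0) stop("'dt' must be non-negative")
  out <- probs + dt * as.vector(rate_matrix %*% probs)
  if (any(out < 0))
    stop("negative state probability after step; reduce 'dt'")
  out
}

#' Equilibrium occupancy of a sensor without the fusion transition
#'
#' Detailed-balance solution of the pure binding/unbinding chain at constant
#' calcium `ca0` (the killing term is excluded):
#' `pi[n+1] / pi[n] = (N - n) k_on ca0 / ((n+1) coop_b^n k_off)`, normalized.
#' At `ca0 = 0` all mass sits in the unbound state.
#'
#' @inheritParams sensor_rate_matrix
#' @param ca0 Resting calcium concentration, uM (>= 0).
#' @return Numeric vector of `n_sites + 1` occupancy probabilities.
#' @export
equilibrium_state <- function(kin, ca0) {
  stopifnot(inherits(kin, "sensor_kinetics"), length(ca0) == 1L)
  if (is.na(ca0) || ca0 < 0) stop("'ca0' must be a non-negative concentration")
  N <- kin$n_sites
  n <- 0:(N - 1L)
  ratio <- (N - n) * kin$k_on * ca0 / ((n + 1L) * kin$coop_b^n * kin$k_off)
  pi_un <- c(1, cumprod(ratio))
  pi_un / sum(pi_un)
}

# Dominant (quasi-stationary) eigen-structure of the killed chain at constant
# calcium, by power iteration with repeated squaring of the one-step matrix
# P = I + dt * T.  P and exp(dt T) share eigenvectors, so the normalized
# dominant eigenvector is the quasi-stationary distribution exactly (up to
# the convergence tolerance), independent of dt.  All entries stay
# non-negative throughout, so relative accuracy is preserved even for
# occupancies many orders of magnitude below one (low-calcium regime).
# Convergence is judged per state, relative, so the tiny fully-bound
# occupancy that sets the release rate has converged too.
.qs_state <- function(kin, ca0, tol = 1e-12, max_doublings = 400L) {
  Tm <- sensor_rate_matrix(kin, ca0)
  dt <- min(0.005, 0.25 / max(abs(diag(Tm))))
  P <- diag(nrow(Tm)) + dt * Tm
  s <- equilibrium_state(kin, ca0)
  for (i in seq_len(max_doublings)) {
    s_new <- as.vector(P %*% s)
    tot <- sum(s_new)
    if (tot <= 0) stop("quasi-stationary iteration lost all probability mass")
    s_new <- s_new / tot
    rel <- max(abs(s_new - s) / pmax(s_new, 1e-300))
    if (rel < tol) return(s_new)
    s <- s_new
    P <- P %*% P
    P <- P / max(P)       # renormalized propagation is scale invariant
  }
  stop("quasi-stationary iteration did not converge within the horizon")
}

#' Quasi-stationary distribution of a sensor at constant calcium
#'
#' The limiting state distribution of the killed sensor chain conditioned on
#' no fusion having occurred (the renormalized propagation's fixed point).
#' Used to initialize trace-driven runs so the conditional release rate
#' starts at its resting value.
#'
#' @inheritParams equilibrium_state
#' @return Numeric vector of `n_sites + 1` conditional occupancies.
#' @export
quasi_stationary_state <- function(kin, ca0) {
  if (ca0 == 0) {
    s <- numeric(kin$n_sites + 1L); s[1L] <- 1
    return(s)
  }
  .qs_state(kin, ca0)
}

#' Quasi-stationary (spontaneous) release rate at constant calcium
#'
#' Asymptotic conditional release rate `gamma_fuse * s_N` under renormalized
#' propagation of the killed chain held at constant calcium `ca0`.  This is
#' the model's steady-state spontaneous release rate; for the shipped Syt-1
#' and Syt-7 kinetics at 0.1 uM it evaluates to ~5.9e-9 and ~1.9e-5 per ms.
#' The default algorithm is renormalized power iteration (converged to
#' relative changes below `tol`); `method = "eigen"` solves the killed
#' generator's dominant eigenvector directly as an independent cross-check.
#'
#' @inheritParams equilibrium_state
#' @param method `"iterate"` (renormalized power iteration, default) or
#'   `"eigen"` (direct eigen-solve of the killed generator).
#' @param tol Convergence tolerance on the state distribution (iterate only).
#' @return Release rate in 1/ms.
#' @export
quasi_stationary_rate <- function(kin, ca0, method = c("iterate", "eigen"),
                                  tol = 1e-14) {
  method <- match.arg(method)
  if (ca0 == 0) return(0)
  N1 <- kin$n_sites + 1L
  if (method == "iterate") {
    s <- .qs_state(kin, ca0, tol = tol)
  } else {
    Tm <- sensor_rate_matrix(kin, ca0)
    eg <- eigen(Tm)
    i <- which.max(Re(eg$values))
    v <- Re(eg$vectors[, i])
    if (all(v <= 0)) v <- -v
    if (any(v < -1e-10 * max(abs(v))))
      stop("dominant eigenvector is not sign-definite")
    s <- pmax(v, 0) / sum(pmax(v, 0))
  }
  kin$gamma_fuse * s[N1]
}

#' Propagate renormalized sensor state probabilities along a calcium trace
#'
#' First-order propagation `s <- (I + dt * T(ca(t))) s` followed by
#' renormalization `s <- s / sum(s)` at every internal step, so the state
#' vector tracks occupancies conditioned on no fusion yet.  The calcium trace
#' is linearly interpolated onto the internal `dt` grid; the returned
#' trajectory is sampled back on the trace's own grid.
#'
#' @inheritParams sensor_rate_matrix
#' @param trace A [ca_trace()] object.
#' @param dt Internal propagation step, ms (default 0.005).
#' @param init Initial state probabilities; default is the quasi-stationary
#'   state at the trace's first value.
#' @return A list with `time` (ms, the trace grid), `probs` (matrix, one row
#'   per time point, `n_sites + 1` columns) and `rate` (conditional release
#'   rate `gamma_fuse * s_N`, 1/ms).
#' @export
propagate_renormalized <- function(kin, trace, dt = 0.005, init = NULL) {
  stopifnot(inherits(kin, "sensor_kinetics"), inherits(trace, "ca_trace"))
  if (dt <= 0) stop("'dt' must be positive")
  if (is.null(init)) init <- quasi_stationary_state(kin, trace$values[1L])
  N1 <- kin$n_sites + 1L
  if (length(init) != N1 || any(init < 0))
    stop("'init' must be a valid state-probability vector")
  s <- init / sum(init)

  t_grid <- ca_trace_times(trace)
  n_rec <- length(t_grid)
  # internal fine grid; each record time is hit by construction
  n_sub <- max(1L, as.integer(round(trace$dt / dt)))
  dt_eff <- trace$dt / n_sub
  ca_rec <- trace$values

  probs <- matrix(NA_real_, n_rec, N1)
  probs[1L, ] <- s
  kon <- kin$k_on; N <- kin$n_sites
  nvec <- 0:(N - 1L)
  unbind <- (nvec + 1L) * kin$coop_b^nvec * kin$k_off
  kill <- c(rep(0, N), kin$gamma_fuse)
  for (i in seq_len(n_rec - 1L)) {
    ca0 <- ca_rec[i]; ca1 <- ca_rec[i + 1L]
    for (j in seq_len(n_sub)) {
      frac <- (j - 1L) / n_sub
      ca <- ca0 + frac * (ca1 - ca0)
      bind <- (N - nvec) * kon * ca
      # ds/dt assembled without forming the matrix (tridiagonal structure)
      flow_up <- bind * s[1:N]
      flow_dn <- unbind * s[2:N1]
      ds <- c(flow_dn, 0) - c(0, flow_dn) + c(0, flow_up) - c(flow_up, 0) -
        kill * s
      s <- s + dt_eff * ds
      if (any(s < 0))
        stop(sprintf("negative state probability at t = %g ms; reduce 'dt'",
                     t_grid[i] + (j - 1L) * dt_eff))
      s <- s / sum(s)
    }
    probs[i + 1L, ] <- s
  }
  list(time = t_grid, probs = probs, rate = kin$gamma_fuse * probs[, N1])
}

#' Conditional release-rate trace of a sensor driven by a calcium trace
#'
#' Convenience wrapper around [propagate_renormalized()] returning the
#' conditional (hazard) release rate `gamma_fuse * s_N(t)` on the trace grid.
#' The rate is bounded by `[0, gamma_fuse]` everywhere and, for a constant
#' trace, converges to [quasi_stationary_rate()].
#'
#' @inheritParams propagate_renormalized
#' @return A data frame with columns `time_ms` and `rate_per_ms`.
#' @export
conditional_release_trace <- function(kin, trace, dt = 0.005, init = NULL) {
  run <- propagate_renormalized(kin, trace, dt = dt, init = init)
  data.frame(time_ms = run$time, rate_per_ms = run$rate)
}
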