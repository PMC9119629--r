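# Independent numerical oracles used across the test files.

# Convolution of the unit-mass exponential decay (1/tau) exp(-u/tau) u(u)
# with the ex-Gaussian filter, by adaptive quadrature at each time point.
conv_filtered_oracle <- function(t, tau, k, mu, sigma) {
  vapply(t, function(ti) {
    stats::integrate(function(s)
      ex_gaussian_pdf(s, k, mu, sigma) *
        ifelse(ti - s >= 0, exp(-(ti - s) / tau) / tau, 0),
      lower = mu - 10 * sigma - 10 / k, upper = ti,
      rel.tol = 1e-11, subdivisions = 400L)$value
  }, 0)
}

# Convolution of the exponential density (rate k) with the normal density,
# by quadrature: the ex-Gaussian density itself.
conv_exgauss_oracle <- function(t, k, mu, sigma) {
  vapply(t, function(ti) {
    stats::integrate(function(s)
      ifelse(s >= 0, k * exp(-k * s), 0) * stats::dnorm(ti - s, mu, sigma),
      lower = 0, upper = max(0, ti - mu + 12 * sigma) + 30 / k,
      rel.tol = 1e-11, subdivisions = 400L)$value
  }, 0)
}

# Exact quasi-stationary release rate by the flux-corrected recursion:
# at stationarity conditioned on survival, the net upward flux through the
# link n -> n+1 equals the killed flux times the probability mass at or
# below n.  Solving v_{n+1} = (lambda_n v_n - F C_n) / mu_{n+1} with
# F = gamma v_N / sum(v) is a one-dimensional root-find, independent of the
# package's power-iteration and eigen routes.
flux_recursion_rate <- function(kin, ca) {
  N <- kin$n_sites
  n <- 0:(N - 1L)
  lam <- (N - n) * kin$k_on * ca
  mu <- (n + 1L) * kin$coop_b^n * kin$k_off
  g <- function(logF) {
    F <- exp(logF)
    v <- 1
    C <- 1
    for (m in 1:N) {
      v[m + 1L] <- (lam[m] * v[m] - F * C) / mu[m]
      if (v[m + 1L] <= 0) return(-1)
      C <- C + v[m + 1L]
    }
    log(kin$gamma_fuse * v[N + 1L] / sum(v)) - logF
  }
  eq <- equilibrium_state(kin, ca)
  hi <- log(kin$gamma_fuse * eq[N + 1L])
  exp(stats::uniroot(g, c(hi - 40, hi), tol = 1e-14)$root)
}

# Equilibrium-restricted flux-balance approximation (upper bound on the
# quasi-stationary rate: it neglects the depression of the chain by the
# net upward flux).
flux_balance_rate <- function(kin, ca) {
  N <- kin$n_sites
  # equilibrium of the chain restricted to states 0..N-1
  n <- 0:(N - 2L)
  ratio <- (N - n) * kin$k_on * ca / ((n + 1L) * kin$coop_b^n * kin$k_off)
  pi_un <- c(1, cumprod(ratio))
  pi_r <- pi_un / sum(pi_un)
  lam_top <- kin$k_on * ca                       # N-1 -> N binding rate
  mu_top <- N * kin$coop_b^(N - 1L) * kin$k_off  # N -> N-1 unbinding rate
  pi_r[N] * lam_top * kin$gamma_fuse / (kin$gamma_fuse + mu_top)
}

# Exact-step renormalized propagation using the matrix exponential.
expm_renorm_trajectory <- function(kin, ca, dt, n_steps, init) {
  Tm <- sensor_rate_matrix(kin, ca)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(dt * Tm)))
  out <- matrix(NA_real_, n_steps + 1L, length(init))
  s <- init / sum(init)
  out[1L, ] <- s
  for (i in seq_len(n_steps)) {
    s <- as.vector(P %*% s)
    s <- s / sum(s)
    out[i + 1L, ] <- s
  }
  out
}
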