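# Independent reference implementations used as oracles.  These deliberately
# avoid the package's own integration paths (fine-step explicit integration,
# closed forms, event-by-event simulation).

# Fine-step reference integration of the AdEx membrane equation (no spike
# mechanism; subthreshold only), exponential term included.
ref_adex_subthreshold <- function(V0, params, I = 0, t_max = 100,
                                  dt = 0.001) {
  p <- as.list(params)
  n <- round(t_max / dt)
  V <- numeric(n + 1)
  V[1] <- V0
  for (k in seq_len(n)) {
    dV <- (-p$g_L * (V[k] - p$E_L) +
             p$g_L * p$Delta_T * exp((V[k] - p$V_t) / p$Delta_T) + I) / p$C_m
    V[k + 1] <- V[k] + dt * dV
  }
  data.frame(time = (0:n) * dt, V = V)
}

# Event-by-event Tsodyks-Markram oracle: exact exponential decay between
# spikes, jump rule at spikes.  Returns state just after the last spike.
ref_stp_train <- function(spike_times, U = 0.2, tau_A = 5000, tau_D = 280) {
  u <- 0; x <- 1; t_last <- NULL
  for (t in spike_times) {
    if (!is.null(t_last)) {
      del <- t - t_last
      u <- u * exp(-del / tau_A)
      x <- 1 - (1 - x) * exp(-del / tau_D)
    }
    u <- u + U * (1 - u)
    x <- x - U * x
    t_last <- t
  }
  list(u = u, x = x)
}

# Fine-step integration of the Z/P trace cascade over a spike train given as
# spike times (ms).
ref_bcpnn_traces <- function(pre_spikes, post_spikes, t_max, tau_z = 100,
                             tau_p = 15000, eps = 0.0026, f_max = 25,
                             t_spike = 1, kappa = 1, dt = 0.01) {
  n <- round(t_max / dt)
  drive <- 1 / (f_max * 1e-3 * t_spike)
  S <- function(spikes) {
    s <- rep(0, n)
    for (t in spikes) {
      a <- floor(t / dt) + 1
      b <- min(n, a + round(t_spike / dt) - 1)
      if (a <= n) s[a:b] <- 1
    }
    s
  }
  Si <- S(pre_spikes); Sj <- S(post_spikes)
  Zi <- Zj <- eps; Pi <- Pj <- eps; Pij <- eps^2
  for (k in seq_len(n)) {
    Zi <- Zi + dt / tau_z * (drive * Si[k] - Zi + eps)
    Zj <- Zj + dt / tau_z * (drive * Sj[k] - Zj + eps)
    Pi <- Pi + kappa * dt / tau_p * (Zi - Pi)
    Pj <- Pj + kappa * dt / tau_p * (Zj - Pj)
    Pij <- Pij + kappa * dt / tau_p * (Zi * Zj - Pij)
  }
  list(Z_i = Zi, Z_j = Zj, P_i = Pi, P_j = Pj, P_ij = Pij)
}

# Closed-form peak of a passive-membrane PSP for one exponential conductance
# (linearised around the holding potential; valid for small deflections).
ref_psp_peak_linear <- function(g, tau_s, E_rev, hold, params) {
  p <- as.list(params)
  g_eff <- p$g_L - p$g_L * exp((hold - p$V_t) / p$Delta_T)
  tau_m <- p$C_m / g_eff
  D <- E_rev - hold
  if (abs(tau_m - tau_s) < 1e-9) tau_m <- tau_m * (1 + 1e-6)
  t_pk <- log(tau_m / tau_s) / (1 / tau_s - 1 / tau_m)
  amp <- g * D / (g_eff * (tau_m / tau_s - 1))
  amp * (exp(-t_pk / tau_m) - exp(-t_pk / tau_s))
}
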