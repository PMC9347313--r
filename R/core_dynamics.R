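# Reference (R-level) implementations of the single-neuron and single-synapse
# kernels.  The network engine implements the same update rules in compiled
# code; these functions define the contract and serve small-scale analysis.

#' Initial AdEx neuron state
#'
#' @param params neuron parameters, see [neuron_params()]
#' @param V_m initial membrane potential (mV); defaults to the leak reversal
#' @param I_bias intrinsic excitability current (pA)
#' @export
neuron_state <- function(params = neuron_params(), V_m = params[["E_L"]],
                         I_w = 0, refractory = 0, I_bias = 0) {
  list(V_m = V_m, I_w = I_w, refractory = refractory, I_bias = I_bias)
}

#' One forward-Euler step of the AdEx neuron
#'
#' Integrates the membrane equation with the exponential upstroke term and
#' the adaptation current.  A spike is registered when the membrane crosses
#' the numeric detection ceiling; the potential is then reset, the
#' adaptation current incremented by `b`, and the refractory clock armed,
#' during which the membrane is clamped at the reset potential.  The
#' adaptation current decays at all times.  Synaptic current follows the
#' convention of [synaptic_current()] (positive = hyperpolarising) and enters
#' with a minus sign.
#'
#' @param state neuron state, see [neuron_state()]
#' @param params neuron parameters
#' @param I_syn total synaptic current (pA), sign per [synaptic_current()]
#' @param I_ext external injected current (pA)
#' @param dt integration step (ms)
#' @param spike_ceiling detection ceiling (mV)
#' @return list with the updated `state` and logical `spiked`
#' @export
adex_step <- function(state, params, I_syn = 0, I_ext = 0, dt = 0.1,
                      spike_ceiling = 0) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive and finite")
  if (!all(is.finite(c(state$V_m, state$I_w, state$refractory, state$I_bias,
                       I_syn, I_ext))))
    stop("state and inputs must be finite")
  p <- as.list(params)
  state$I_w <- state$I_w - dt * state$I_w / p$tau_Iw
  spiked <- FALSE
  if (state$refractory > 0) {
    state$V_m <- p$V_r
    state$refractory <- max(0, state$refractory - dt)
  } else {
    dV <- (-p$g_L * (state$V_m - p$E_L) +
             p$g_L * p$Delta_T * exp((state$V_m - p$V_t) / p$Delta_T) -
             state$I_w + state$I_bias + I_ext - I_syn) / p$C_m
    state$V_m <- state$V_m + dt * dV
    if (state$V_m >= spike_ceiling) {
      spiked <- TRUE
      state$V_m <- p$V_r
      state$I_w <- state$I_w + p$b
      state$refractory <- p$tau_ref
    }
  }
  list(state = state, spiked = spiked)
}

#' Conductance-based synaptic current
#'
#' Returns `sum(g * (V_m - E_rev))` over the active receptors, in pA for
#' conductances in nS and potentials in mV.  With this sign convention the
#' value is positive (hyperpolarising) for GABA above its reversal and
#' negative (depolarising) for AMPA/NMDA below theirs; it enters the
#' membrane equation of [adex_step()] with a minus sign.
#'
#' @param V_m membrane potential (mV)
#' @param conductances named numeric vector of conductances (nS); names must
#'   be receptor labels known to `receptors`
#' @param receptors receptor kinetics, see [receptor_params()]
#' @export
synaptic_current <- function(V_m, conductances,
                             receptors = receptor_params()) {
  if (length(conductances) == 0) return(0)
  if (is.null(names(conductances)) ||
      !all(names(conductances) %in% names(receptors$E_rev)))
    stop("unknown receptor label in conductances")
  if (any(conductances < 0)) stop("conductances must be non-negative")
  sum(conductances * (V_m - receptors$E_rev[names(conductances)]))
}

#' One step of the Tsodyks-Markram short-term plasticity state
#'
#' Between spikes the utilization `u` decays toward 0 with `tau_A` and the
#' resource fraction `x` recovers toward 1 with `tau_D` (integrated exactly
#' over `dt`).  On a presynaptic spike `u` jumps by `U * (1 - u)` and `x` is
#' depleted by `U * x`.  The conductance factor transmitted by that spike is
#' `u * x` with `u` after its jump and `x` before depletion (returned as
#' `release`).
#'
#' @param state list with `u` and `x`
#' @param params see [stp_params()]
#' @param spike logical, presynaptic spike in this step
#' @param dt step (ms)
#' @return list with updated `u`, `x` and `release` (NA when no spike)
#' @export
stp_update <- function(state, params = stp_params(), spike = FALSE,
                       dt = 0.1) {
  u <- state$u; x <- state$x
  stopifnot(u >= 0, u <= 1, x >= 0, x <= 1)
  u <- u * exp(-dt / params$tau_A)
  x <- 1 - (1 - x) * exp(-dt / params$tau_D)
  release <- NA_real_
  if (isTRUE(spike)) {
    u <- if (params$augmentation) u + params$U * (1 - u) else params$U
    release <- u * x
    x <- x - params$U * x
  }
  list(u = u, x = x, release = release)
}

#' Zero-mean Poisson background conductance events
#'
#' Two independent Poisson generators per target with opposing driving
#' potentials: one delivers `g_unit` at the glutamatergic reversal
#' (excitatory stream), the other `g_unit` at the GABA reversal (inhibitory
#' stream).  The rate applies to each generator.
#'
#' @param rate event rate per generator (Hz)
#' @param g_unit event conductance magnitude (nS)
#' @param duration stream duration (ms)
#' @param dt time resolution (ms)
#' @param seed RNG seed
#' @return data.frame with `time` (ms), `stream` ("exc"/"inh"), `g` (nS) and
#'   `E_rev` (mV)
#' @export
poisson_background <- function(rate, g_unit = 1.5, duration = 1000,
                               dt = 0.1, seed = 1) {
  if (!is.finite(rate) || rate < 0) stop("rate must be non-negative")
  receptors <- receptor_params()
  n <- floor(duration / dt)
  p <- rate * 1e-3 * dt
  set.seed(seed)
  t_exc <- which(runif(n) < p) * dt
  t_inh <- which(runif(n) < p) * dt
  n_ev <- length(t_exc) + length(t_inh)
  out <- data.frame(
    time = c(t_exc, t_inh),
    stream = rep(c("exc", "inh"), c(length(t_exc), length(t_inh))),
    g = rep(g_unit, n_ev),
    E_rev = unname(rep(receptors$E_rev[c("AMPA", "GABA")],
                       c(length(t_exc), length(t_inh)))),
    row.names = NULL)
  out[order(out$time), , drop = FALSE]
}

#' Steady-state short-term-plasticity state under baseline firing
#'
#' Fixed point of the utilization/resource dynamics under periodic firing
#' at a low baseline rate.  Trials start from this state rather than from
#' the fully naive `(u = 0, x = 1)`: the augmentation time constant (5 s)
#' is far longer than any reasonable settling period, and an ongoing
#' network has its synapses equilibrated to its baseline activity.
#'
#' @param params see [stp_params()]
#' @param rate baseline firing rate (Hz)
#' @return list with `u` and `x` at the fixed point
#' @export
stp_baseline_state <- function(params = stp_params(), rate = 1) {
  if (rate <= 0) return(list(u = 0, x = 1))
  isi <- 1000 / rate
  dA <- exp(-isi / params$tau_A)
  dD <- exp(-isi / params$tau_D)
  U <- params$U
  # u_{n+1} = (u_n + U (1 - u_n)) dA ; x_{n+1} = 1 - (1 - (1-U) x_n) dD
  u <- if (params$augmentation) U * dA / (1 - (1 - U) * dA) else U
  x <- (1 - dD) / (1 - (1 - U) * dD)
  list(u = u, x = x)
}

#' Subthreshold fixed point of the AdEx membrane
#'
#' Solves `g_L (V - E_L) = g_L Delta_T exp((V - V_t) / Delta_T)` for the
#' resting potential with all inputs at zero, by root finding.
#'
#' @param params neuron parameters
#' @export
adex_fixed_point <- function(params = neuron_params()) {
  p <- as.list(params)
  f <- function(V) -p$g_L * (V - p$E_L) +
    p$g_L * p$Delta_T * exp((V - p$V_t) / p$Delta_T)
  uniroot(f, lower = p$E_L - 10, upper = p$V_t - 1e-6, tol = 1e-12)$root
}
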