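# Spike-based BCPNN learning rule: Z/P trace cascades, log-odds weights,
# log-prior bias, and kappa-gated learning-rate modulation.

#' Fresh BCPNN trace state
#'
#' Traces start at the naive prior: `P_i = P_j = eps`, `P_ij = eps^2`, so the
#' initial associative weight is exactly zero and the initial bias is
#' `beta_gain * log(eps)`.  All traces stay at or above their floors
#' (`eps` for Z/P_i/P_j, `eps^2` for P_ij) under the update equations.
#'
#' @param params see [bcpnn_params()]
#' @export
bcpnn_traces <- function(params = bcpnn_params()) {
  e <- params$eps
  list(Z_i = e, Z_j = e, P_i = e, P_j = e, P_ij = e * e)
}

#' Integrate a Z trace over a binary spike stream
#'
#' `tau_z dZ/dt = S / (f_max t_spike) - Z + eps`, where `S` is 1 during a
#' rectangular pulse of `t_spike` after each spike and 0 otherwise.  The
#' normalisation by the maximal rate calibrates the trace so that sustained
#' firing at `f_max` saturates the time-averaged Z near 1, while with no
#' spikes Z decays to `eps`.
#'
#' @param z0 initial trace value
#' @param spikes logical/0-1 vector, one entry per step
#' @param tau_z trace time constant (ms)
#' @param params see [bcpnn_params()]
#' @param dt step (ms)
#' @return numeric vector of trace values after each step
#' @export
z_update <- function(z0, spikes, tau_z, params = bcpnn_params(), dt = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  spikes <- as.integer(spikes != 0)
  pulse <- max(1L, round(params$t_spike / dt))
  # S = 1 within t_spike of a spike
  S <- as.integer(filter(c(spikes, rep(0L, pulse - 1L)),
                         rep(1, pulse), sides = 1)[seq_along(spikes)] > 0)
  S[is.na(S)] <- 0L
  drive <- 1 / (params$f_max * 1e-3 * params$t_spike)
  a <- dt / tau_z
  # Z_{k+1} = (1 - a) Z_k + a (drive * S_k + eps)
  z <- filter(a * (drive * S + params$eps), 1 - a, method = "recursive",
              init = z0)
  as.numeric(z)
}

#' Integrate P traces from Z traces
#'
#' `tau_p dP_i/dt = kappa (Z_i - P_i)` (same for `P_j`), and
#' `tau_p dP_ij/dt = kappa (Z_i Z_j - P_ij)`.  With `kappa = 0` the traces
#' (and hence weights and biases) are frozen exactly.
#'
#' @param p0 list with `P_i`, `P_j`, `P_ij` initial values
#' @param Z_i,Z_j Z-trace series (equal length)
#' @param params see [bcpnn_params()]
#' @param kappa learning-rate gain; defaults to `params$kappa`
#' @param dt step (ms)
#' @return list of series `P_i`, `P_j`, `P_ij`
#' @export
p_update <- function(p0, Z_i, Z_j, params = bcpnn_params(),
                     kappa = params$kappa, dt = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(length(Z_i) == length(Z_j))
  a <- kappa * dt / params$tau_p
  if (a == 0) {
    n <- length(Z_i)
    return(list(P_i = rep(p0$P_i, n), P_j = rep(p0$P_j, n),
                P_ij = rep(p0$P_ij, n)))
  }
  rec <- function(x, init) as.numeric(
    filter(a * x, 1 - a, method = "recursive", init = init))
  list(P_i = rec(Z_i, p0$P_i), P_j = rec(Z_j, p0$P_j),
       P_ij = rec(Z_i * Z_j, p0$P_ij))
}

#' BCPNN weight and bias from P traces
#'
#' `w_ij = w_gain * log(P_ij / (P_i P_j))` and
#' `beta_j = beta_gain * log(P_j)`.  Weights may be negative (rendered as
#' inhibition on delivery, see [apply_plastic_weight()]).
#'
#' @param traces list with `P_i`, `P_j`, `P_ij` (vectors allowed)
#' @param params see [bcpnn_params()]
#' @param receptor which gain bank to use, "AMPA" or "NMDA"
#' @return list with `w` (nS) and `beta` (pA)
#' @export
weight_and_bias <- function(traces, params = bcpnn_params(),
                            receptor = "NMDA") {
  with(traces, {
    if (any(c(P_i, P_j, P_ij) <= 0))
      stop("P traces must be positive for the log-odds weight")
    list(w = params$w_gain[[receptor]] * log(P_ij / (P_i * P_j)),
         beta = params$beta_gain * log(P_j))
  })
}

#' Conductance routing of a signed plastic weight
#'
#' BCPNN log-odds weights can be negative.  A positive weight is delivered
#' as conductance at the excitatory reversal of its receptor bank; a
#' negative weight is delivered as `|w|` at the GABA reversal, rendering the
#' learned disynaptic inhibition between weakly coupled populations
#' monosynaptically.
#'
#' @param w signed weight (nS)
#' @param receptor receptor bank of the weight, "AMPA" or "NMDA"
#' @return list with `receptor` (delivery channel) and `g` (non-negative
#'   conductance, nS); `g = 0` means no conductance event
#' @export
apply_plastic_weight <- function(w, receptor = "AMPA") {
  if (w >= 0) list(receptor = receptor, g = w)
  else list(receptor = "GABA", g = -w)
}

#' Set the plasticity modulation kappa on a network
#'
#' Overrides the learning-rate gain for selected associative connections
#' (and the bias traces of the listed neurons) for the whole of subsequent
#' simulations of the network.  Transient, epoch-limited modulation (the
#' kappa-boost protocol) is expressed through the schedule instead, see
#' [build_schedule()].
#'
#' @param net a `semnet_network`
#' @param kappa non-negative learning-rate gain; 0 freezes plasticity
#' @param synapses indices into the network synapse table (default: all
#'   plastic synapses)
#' @param neurons neuron ids whose bias traces follow the new kappa
#'   (default: all pyramidal cells)
#' @export
set_kappa <- function(net, kappa, synapses = NULL, neurons = NULL) {
  stopifnot(inherits(net, "semnet_network"))
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be non-negative")
  if (is.null(synapses)) synapses <- which(net$synapses$plastic)
  if (is.null(neurons))
    neurons <- net$neurons$id[net$neurons$type == "pyr"]
  net$kappa_overrides <- c(net$kappa_overrides,
                           list(list(kappa = kappa, synapses = synapses,
                                     neurons = neurons)))
  net
}

#' Tabulate BCPNN trace state of a trial for checkpointing
#'
#' @param trial a `semnet_trial` result
#' @return data.frame with one row per plastic connection and columns
#'   `connection`, `pre`, `post`, `Z_i`, `Z_j` and the P traces of both
#'   receptor banks
#' @export
bcpnn_trace_table <- function(trial) {
  fs <- trial$final_state
  syn <- trial$plastic_synapses
  data.frame(connection = seq_len(nrow(syn)), pre = syn$pre,
             post = syn$post,
             Z_i_AMPA = fs$Za[syn$pre], Z_j_AMPA = fs$Za[syn$post],
             Z_i_NMDA = fs$Zn[syn$pre], Z_j_NMDA = fs$Zn[syn$post],
             P_i_AMPA = fs$traces[, 1], P_j_AMPA = fs$traces[, 2],
             P_ij_AMPA = fs$traces[, 3], P_i_NMDA = fs$traces[, 4],
             P_j_NMDA = fs$traces[, 5], P_ij_NMDA = fs$traces[, 6])
}
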