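# Multiplicative nearest-neighbour STDP for the associative pathway.

#' STDP weight update for a single pairing
#'
#' Potentiation branch `lambda (1 - w)^mu_plus exp(-|dt|/tau_plus)` when the
#' postsynaptic spike follows the delayed presynaptic arrival
#' (`delta_t >= 0`, or `delta_t >= delay` with the literal branch
#' condition), depression branch `-lambda alpha w^mu_minus
#' exp(-|dt|/tau_minus)` otherwise.  The returned update is clipped so that
#' the normalised weight stays in `[0, 1]`.
#'
#' @param w_norm current normalised weight in `[0, 1]`
#' @param delta_t pairing difference `t_post - (t_pre + delay)` (ms)
#' @param params see [stdp_params()]
#' @param delay transmission delay, only used with `branch_at_delay` (ms)
#' @return weight increment `delta_w`
#' @export
stdp_delta <- function(w_norm, delta_t, params = stdp_params(), delay = 0) {
  if (any(w_norm < 0 | w_norm > 1)) stop("w_norm must lie in [0, 1]")
  thr <- if (params$branch_at_delay) delay else 0
  pot <- delta_t >= thr
  dw <- ifelse(pot,
               params$lambda * (1 - w_norm)^params$mu_plus *
                 exp(-abs(delta_t) / params$tau_plus),
               -params$lambda * params$alpha * w_norm^params$mu_minus *
                 exp(-abs(delta_t) / params$tau_minus))
  pmin(1 - w_norm, pmax(-w_norm, dw))
}

#' Fresh per-synapse STDP state
#' @param params see [stdp_params()]
#' @export
stdp_state <- function(params = stdp_params()) {
  list(w_norm = params$w0, t_pre_arrival = -Inf, t_post = -Inf)
}

#' Process one synaptic event under nearest-neighbour STDP
#'
#' Each event pairs with the most recent opposite event: a presynaptic
#' arrival (the spike time plus the transmission delay) pairs with the last
#' postsynaptic spike (depression), and a postsynaptic spike pairs with the
#' last presynaptic arrival (potentiation).  Events must be delivered in
#' non-decreasing time order per synapse.
#'
#' @param state see [stdp_state()]
#' @param event "pre-arrival" or "post-spike"
#' @param t event time (ms); for "pre-arrival" this is the arrival time,
#'   i.e. spike time plus delay
#' @param params see [stdp_params()]
#' @param delay transmission delay of the synapse (ms)
#' @return updated state
#' @export
stdp_on_spike <- function(state, event = c("pre-arrival", "post-spike"), t,
                          params = stdp_params(), delay = 0) {
  event <- match.arg(event)
  last <- max(state$t_pre_arrival, state$t_post, -Inf)
  if (is.finite(last) && t < last)
    stop("event times must be non-decreasing per synapse")
  if (event == "pre-arrival") {
    if (is.finite(state$t_post)) {
      dtp <- state$t_post - t  # <= 0
      state$w_norm <- state$w_norm +
        stdp_delta(state$w_norm, dtp, params, delay)
    }
    state$t_pre_arrival <- t
  } else {
    if (is.finite(state$t_pre_arrival)) {
      dtp <- t - state$t_pre_arrival  # >= 0
      state$w_norm <- state$w_norm +
        stdp_delta(state$w_norm, dtp, params, delay)
    }
    state$t_post <- t
  }
  state$w_norm <- min(1, max(0, state$w_norm))
  state
}

#' Delivered conductance of an STDP synapse
#'
#' @param w_norm normalised weight
#' @param params see [stdp_params()]
#' @return named vector of conductances (nS) per receptor
#' @export
stdp_conductance <- function(w_norm, params = stdp_params()) {
  c(AMPA = w_norm * params$w_max[["AMPA"]],
    NMDA = w_norm * params$w_max[["NMDA"]])
}
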