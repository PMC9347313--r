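# Internal bridge between R-level model objects and the compiled engine.

.engine_kind <- c(rec_exc = 0L, rec_inh = 1L, pyr_ba = 0L, ba_pyr = 1L,
                  assoc = 2L)

.bcpnn_par_vec <- function(bc, bias_mode, static_bias = 0,
                           bias_p0 = bc$eps) {
  c(eps = bc$eps, f_max = bc$f_max, t_spike = bc$t_spike,
    tau_z_AMPA = bc$tau_z[["AMPA"]], tau_z_NMDA = bc$tau_z[["NMDA"]],
    tau_p = bc$tau_p, w_gain_AMPA = bc$w_gain[["AMPA"]],
    w_gain_NMDA = bc$w_gain[["NMDA"]], beta_gain = bc$beta_gain,
    bias_mode = bias_mode, static_bias = static_bias, bias_p0 = bias_p0)
}

.stdp_par_vec <- function(sp) {
  c(lambda = sp$lambda, alpha = sp$alpha, tau_plus = sp$tau_plus,
    tau_minus = sp$tau_minus, w0 = sp$w0,
    w_max_AMPA = sp$w_max[["AMPA"]], w_max_NMDA = sp$w_max[["NMDA"]],
    mu_plus = sp$mu_plus, mu_minus = sp$mu_minus,
    branch_at_delay = as.numeric(sp$branch_at_delay))
}

# Run the compiled engine.  All times in ms; neuron/synapse indices 1-based
# on the R side, converted here.
.simulate <- function(group, params, synapses, rule, t_total,
                      noise = data.frame(t = 0, rate_pyr = 0,
                                         rate_basket = 0),
                      g_bg = 1.5, stim = list(), currents = list(),
                      kappa_epochs = list(), kappa_default = 1,
                      snapshots_ms = numeric(), tracked = integer(),
                      traced = integer(), raster = TRUE, interval_ms = 1,
                      init_state = list(), seed = 1, augmentation = NULL,
                      bias_mode = NULL, static_bias = NULL,
                      bias_p0 = NULL) {
  dt <- params$sim$dt
  n_steps <- round(t_total / dt)
  rule_i <- switch(rule, none = 0L, bcpnn = 1L, stdp = 2L)
  if (is.null(bias_mode)) bias_mode <- if (rule == "bcpnn") 1L else 2L
  if (is.null(bias_p0)) bias_p0 <- params$bcpnn$eps
  if (is.null(static_bias))
    static_bias <- params$bcpnn$beta_gain * log(bias_p0)
  if (is.null(augmentation)) augmentation <- params$stp$augmentation

  syn <- list(pre = as.integer(synapses$pre - 1L),
              post = as.integer(synapses$post - 1L),
              delay = pmax(1L, as.integer(round(synapses$delay / dt))),
              kind = unname(.engine_kind[synapses$class]),
              stp = as.integer(synapses$stp),
              wA = as.numeric(synapses$wA), wN = as.numeric(synapses$wN),
              wG = as.numeric(synapses$wG))

  rec <- params$receptor
  receptor <- c(tau_AMPA = rec$tau_syn[["AMPA"]],
                tau_NMDA = rec$tau_syn[["NMDA"]],
                tau_GABA = rec$tau_syn[["GABA"]],
                E_AMPA = rec$E_rev[["AMPA"]], E_NMDA = rec$E_rev[["NMDA"]],
                E_GABA = rec$E_rev[["GABA"]])
  stp_par <- c(U = params$stp$U, tau_A = params$stp$tau_A,
               tau_D = params$stp$tau_D,
               augmentation = as.numeric(augmentation))

  noise_l <- list(t_start = as.integer(round(noise$t / dt)),
                  rate_pyr = as.numeric(noise$rate_pyr),
                  rate_basket = as.numeric(noise$rate_basket),
                  g_exc = g_bg, g_inh = g_bg)
  stim_l <- lapply(stim, function(e) list(
    start = as.integer(round(e$start / dt)),
    end = as.integer(round(e$end / dt)), rate = e$rate, g = e$g,
    targets = as.integer(e$targets - 1L)))
  cur_l <- lapply(currents, function(e) list(
    start = as.integer(round(e$start / dt)),
    end = as.integer(round(e$end / dt)), amp = e$amp,
    period = as.integer(round((e$period %||% 0) / dt)),
    width = as.integer(round((e$width %||% 0) / dt)),
    targets = as.integer(e$targets - 1L)))
  kap_l <- lapply(kappa_epochs, function(e) list(
    start = as.integer(round(e$start / dt)),
    end = as.integer(round(e$end / dt)), kappa = e$kappa,
    synapses = as.integer((e$synapses %||% integer()) - 1L),
    neurons = as.integer((e$neurons %||% integer()) - 1L)))

  record <- list(snapshot_steps = as.integer(sort(round(snapshots_ms / dt))),
                 tracked_syn = as.integer(tracked - 1L),
                 trace_syn = as.integer(traced - 1L),
                 raster = isTRUE(raster), interval_ms = interval_ms)

  out <- .engine_simulate(n_steps, dt, as.integer(group),
                          unclass(params$neuron), unclass(params$basket),
                          receptor, syn, stp_par, rule_i,
                          .bcpnn_par_vec(params$bcpnn, bias_mode,
                                         static_bias, bias_p0),
                          .stdp_par_vec(params$stdp), kappa_default, kap_l,
                          noise_l, stim_l, cur_l, record, init_state,
                          as.double(seed %% 2^31))
  out$spike_id <- out$spike_id + 1L
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
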