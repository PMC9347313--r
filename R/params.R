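#' Neuron model parameters
#'
#' Parameters of the adaptive exponential integrate-and-fire (AdEx) neuron.
#' Defaults are the parameter-table values used for every cell in the model;
#' subthreshold adaptation is not part of this variant.
#'
#' @param C_m membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param E_L leak reversal potential (mV)
#' @param Delta_T upstroke slope factor (mV)
#' @param V_t spike threshold (mV)
#' @param V_r spike reset potential (mV)
#' @param b spike-triggered adaptation increment (pA)
#' @param tau_Iw adaptation current decay time constant (ms)
#' @param tau_ref absolute refractory period (ms)
#' @return named numeric vector of class `semnet_neuron_params`
#' @examples
#' neuron_params()            # pyramidal defaults
#' neuron_params(b = 0)       # fast-spiking basket variant
#' @export
neuron_params <- function(C_m = 280, g_L = 14, E_L = -70.6, Delta_T = 3,
                          V_t = -55, V_r = -60, b = 86, tau_Iw = 280,
                          tau_ref = 5) {
  p <- c(C_m = C_m, g_L = g_L, E_L = E_L, Delta_T = Delta_T, V_t = V_t,
         V_r = V_r, b = b, tau_Iw = tau_Iw, tau_ref = tau_ref)
  if (any(!is.finite(p))) stop("neuron parameters must be finite")
  if (C_m <= 0 || g_L <= 0) stop("C_m and g_L must be positive")
  if (tau_Iw <= 0 || tau_ref <= 0) stop("time constants must be positive")
  if (V_r > V_t) stop("V_r must not exceed V_t")
  structure(p, class = "semnet_neuron_params")
}

#' Basket-cell parameters
#'
#' Basket cells use the same AdEx parameter set as pyramidal cells (the
#' model has a single neuron parameter table); spike-triggered adaptation in
#' the basket population absorbs tonic drive while leaving phasic
#' winner-take-all inhibition intact.  A fast-spiking variant without
#' adaptation is available via `b = 0`.
#' @param ... overrides passed to [neuron_params()]
#' @export
basket_params <- function(...) neuron_params(...)

#' Synaptic receptor kinetics
#'
#' Exponential-decay conductance time constants and reversal potentials for
#' the three receptor types.  NMDA differs from AMPA only by its slow decay
#' and its own gain; no voltage-dependent magnesium block is modelled.
#'
#' @param tau_syn named decay time constants (ms) for AMPA, NMDA, GABA
#' @param E_rev named reversal potentials (mV)
#' @return list of class `semnet_receptor_params`
#' @export
receptor_params <- function(tau_syn = c(AMPA = 5, NMDA = 100, GABA = 5),
                            E_rev = c(AMPA = 0, NMDA = 0, GABA = -75)) {
  need <- c("AMPA", "NMDA", "GABA")
  if (!all(need %in% names(tau_syn)) || !all(need %in% names(E_rev)))
    stop("tau_syn and E_rev must name AMPA, NMDA and GABA")
  if (any(tau_syn <= 0)) stop("synaptic time constants must be positive")
  structure(list(tau_syn = tau_syn[need], E_rev = E_rev[need]),
            class = "semnet_receptor_params")
}

#' Tsodyks-Markram short-term plasticity parameters
#'
#' Synaptic augmentation (utilization `u`, decaying with `tau_A`) and
#' depression (resources `x`, recovering with `tau_D`).  Each presynaptic
#' spike jumps `u` by `U * (1 - u)` and depletes `x` by `U * x`; the
#' conductance transmitted by that spike is scaled by `u * x`, with `u` taken
#' after its jump and `x` before depletion.  Setting `augmentation = FALSE`
#' pins `u` to `U` on every spike, removing facilitation while keeping
#' depression.
#'
#' @param U utilization fraction per spike (unitless)
#' @param tau_A augmentation decay time constant (ms)
#' @param tau_D depression recovery time constant (ms)
#' @param augmentation logical; disable to remove the facilitation pathway
#' @export
stp_params <- function(U = 0.2, tau_A = 5000, tau_D = 280,
                       augmentation = TRUE) {
  if (U < 0 || U > 1) stop("U must lie in [0, 1]")
  if (tau_A <= 0 || tau_D <= 0) stop("time constants must be positive")
  structure(list(U = U, tau_A = tau_A, tau_D = tau_D,
                 augmentation = isTRUE(augmentation)),
            class = "semnet_stp_params")
}

#' Spike-based BCPNN learning-rule parameters
#'
#' The Bayesian-Hebbian rule keeps fast Z traces and slow P traces of pre-,
#' post- and co-activation per plastic connection, in two banks (AMPA with
#' `tau_z` 5 ms, NMDA with 100 ms, each with its own weight gain, sharing
#' `tau_p`).  Weights are log-odds `w = w_gain * log(P_ij / (P_i * P_j))` and
#' the intrinsic excitability (bias) current is `beta = beta_gain * log(P_j)`.
#' `kappa` multiplies the P-trace learning rate; `kappa = 0` freezes all
#' weights and biases.  `f_min` appears in the parameter tables of the source
#' model but in no update equation; it is stored, unused by default.
#'
#' @param f_max maximal neuronal spike rate (Hz) used to normalise Z traces
#' @param f_min lowest spiking rate (Hz); stored for completeness, unused
#' @param eps lowest attainable probability estimate (unitless)
#' @param tau_z named Z-trace time constants per receptor bank (ms)
#' @param tau_p P-trace time constant (ms)
#' @param kappa baseline learning-rate gain (1 = regular plasticity)
#' @param kappa_boost modulated learning-rate gain for salient encoding
#' @param w_gain named weight gains per receptor bank (nS)
#' @param beta_gain bias current gain (pA)
#' @param t_spike spike pulse duration in the Z-trace drive (ms)
#' @export
bcpnn_params <- function(f_max = 25, f_min = 0.2, eps = 0.0026,
                         tau_z = c(AMPA = 5, NMDA = 100), tau_p = 15000,
                         kappa = 1, kappa_boost = 2,
                         w_gain = c(AMPA = 0.76, NMDA = 0.07),
                         beta_gain = 40, t_spike = 1) {
  if (eps <= 0 || eps >= 1) stop("eps must lie in (0, 1)")
  if (any(tau_z >= tau_p)) stop("tau_z must be smaller than tau_p")
  if (kappa < 0 || kappa_boost < 0) stop("kappa must be non-negative")
  if (!all(c("AMPA", "NMDA") %in% names(tau_z)) ||
      !all(c("AMPA", "NMDA") %in% names(w_gain)))
    stop("tau_z and w_gain must name AMPA and NMDA banks")
  structure(list(f_max = f_max, f_min = f_min, eps = eps, tau_z = tau_z,
                 tau_p = tau_p, kappa = kappa, kappa_boost = kappa_boost,
                 w_gain = w_gain, beta_gain = beta_gain, t_spike = t_spike),
            class = "semnet_bcpnn_params")
}

#' Multiplicative STDP parameters
#'
#' Nearest-neighbour spike-timing-dependent plasticity with weight-dependent
#' (multiplicative, `mu = 1`) updates.  Internal weights are normalised to
#' `[0, 1]` and scaled by `w_max` per receptor on delivery.  The pairing
#' difference is `delta_t = t_post - (t_pre + delay)`; potentiation applies
#' when the delayed presynaptic arrival precedes the postsynaptic spike.
#' `alpha * tau_minus / tau_plus > 1` guarantees that the integral of the
#' update kernel is negative (stable competitive modification).
#'
#' @param w0 initial normalised weight
#' @param w_max named maximum conductances per receptor (nS)
#' @param lambda learning rate
#' @param alpha potentiation/depression asymmetry
#' @param mu_plus,mu_minus weight-dependence exponents, each 0 or 1
#' @param tau_plus,tau_minus pairing window time constants (ms)
#' @param branch_at_delay logical; use the literal branch condition
#'   `delta_t >= delay` instead of `delta_t >= 0` (see the methods vignette)
#' @export
stdp_params <- function(w0 = 0, w_max = c(AMPA = 13.5, NMDA = 3.5),
                        lambda = 0.01, alpha = 1.2, mu_plus = 1,
                        mu_minus = 1, tau_plus = 20, tau_minus = 20,
                        branch_at_delay = FALSE) {
  if (w0 < 0 || w0 > 1) stop("w0 must lie in [0, 1]")
  if (!mu_plus %in% c(0, 1) || !mu_minus %in% c(0, 1))
    stop("mu exponents must be 0 or 1")
  if (alpha * tau_minus / tau_plus <= 1)
    stop("alpha * tau_minus / tau_plus must exceed 1 (stability condition)")
  if (!all(c("AMPA", "NMDA") %in% names(w_max)))
    stop("w_max must name AMPA and NMDA")
  structure(list(w0 = w0, w_max = w_max, lambda = lambda, alpha = alpha,
                 mu_plus = mu_plus, mu_minus = mu_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus,
                 branch_at_delay = isTRUE(branch_at_delay)),
            class = "semnet_stdp_params")
}

#' Network layout parameters
#'
#' Modular geometry of one cortical patch: hypercolumns (HCs) on a regular
#' grid, each containing `n_mc_per_hc` minicolumns (MCs) of `pyr_per_mc`
#' layer 2/3 pyramidal cells and `basket_per_mc` basket cells.  Two such
#' patches (Item and Context networks) are simulated at
#' `internetwork_distance` from one another.  Memory patterns are
#' non-overlapping: one selective MC per HC per pattern.
#'
#' @param n_hc hypercolumns per network
#' @param n_mc_per_hc minicolumns per hypercolumn
#' @param pyr_per_mc pyramidal cells per minicolumn
#' @param basket_per_mc basket cells per minicolumn
#' @param hc_diameter hypercolumn diameter (mm)
#' @param patch_size patch extent c(x, y) in mm
#' @param internetwork_distance distance between the two networks (mm)
#' @param n_items number of item patterns used by the default task
#' @param n_contexts number of context patterns used by the default task
#' @export
layout_params <- function(n_hc = 12, n_mc_per_hc = 10, pyr_per_mc = 30,
                          basket_per_mc = 2, hc_diameter = 0.5,
                          patch_size = c(2.0, 1.5),
                          internetwork_distance = 10,
                          n_items = 4, n_contexts = 10) {
  if (n_items > n_mc_per_hc || n_contexts > n_mc_per_hc)
    stop("pattern count cannot exceed the number of minicolumns per HC")
  if (any(c(n_hc, n_mc_per_hc, pyr_per_mc, basket_per_mc) < 1))
    stop("layout counts must be positive")
  structure(list(n_hc = n_hc, n_mc_per_hc = n_mc_per_hc,
                 pyr_per_mc = pyr_per_mc, basket_per_mc = basket_per_mc,
                 hc_diameter = hc_diameter, patch_size = patch_size,
                 internetwork_distance = internetwork_distance,
                 n_items = n_items, n_contexts = n_contexts),
            class = "semnet_layout_params")
}

#' Connectivity parameters
#'
#' Connection probabilities and conductances, axonal conduction speeds and
#' the synaptic delay model.  `cp_pp` applies to pyramidal pairs within a
#' hypercolumn, `cp_ppl` to pyramidal pairs in different hypercolumns of the
#' same network, and `cp_ppa` to the sparse plastic associative projections
#' between the two networks (which travel at the myelinated speed).
#'
#' @param cp_pp within-HC pyramidal-pyramidal connection probability
#' @param cp_ppl long-range (cross-HC) pyramidal-pyramidal probability
#' @param cp_ppa associative internetwork probability
#' @param cp_pb,cp_bp pyramidal-basket and basket-pyramidal probabilities
#' @param g_pb pyramidal-to-basket conductance (nS, AMPA)
#' @param g_bp basket-to-pyramidal conductance (nS, negative = GABA)
#' @param speed unmyelinated axonal conduction speed (m/s)
#' @param speed_myel myelinated conduction speed for associative axons (m/s)
#' @param t_min_syn minimal synaptic delay (ms)
#' @param delay_jitter relative SD of the delay distribution
#' @export
connectivity_params <- function(cp_pp = 0.2, cp_ppl = 0.25, cp_ppa = 0.02,
                                cp_pb = 0.7, cp_bp = 0.7, g_pb = 3,
                                g_bp = -7, speed = 0.2, speed_myel = 2,
                                t_min_syn = 1.5, delay_jitter = 0.3) {
  cps <- c(cp_pp, cp_ppl, cp_ppa, cp_pb, cp_bp)
  if (any(cps < 0 | cps > 1)) stop("connection probabilities must be in [0,1]")
  if (speed <= 0 || speed_myel <= 0) stop("conduction speeds must be positive")
  if (t_min_syn < 0) stop("t_min_syn must be non-negative")
  structure(list(cp_pp = cp_pp, cp_ppl = cp_ppl, cp_ppa = cp_ppa,
                 cp_pb = cp_pb, cp_bp = cp_bp, g_pb = g_pb, g_bp = g_bp,
                 speed = speed, speed_myel = speed_myel,
                 t_min_syn = t_min_syn, delay_jitter = delay_jitter),
            class = "semnet_connectivity_params")
}

#' Stimulation protocol parameters
#'
#' Background noise is delivered by two independent Poisson generators per
#' cell with opposing driving potentials (one exciting at the glutamatergic
#' reversal, one at the GABA reversal, equal conductance), applied at the
#' stated rate per generator.  Pattern-specific excitation uses additional
#' Poisson drive during encoding and cueing.
#'
#' @param r_bg_enc background noise rate onto pyramidals during encoding (Hz)
#' @param r_bg_rec background noise rate onto pyramidals during recall (Hz)
#' @param r_bg_basket background noise rate onto basket cells (Hz)
#' @param g_bg background event conductance magnitude (nS)
#' @param t_stim encoding stimulation duration (ms)
#' @param r_stim encoding stimulation rate (Hz)
#' @param isi interstimulus interval between encoding epochs (ms)
#' @param t_cue cue stimulation length (ms)
#' @param r_cue cue stimulation rate (Hz)
#' @param g_stim stimulation and cue conductance (nS)
#' @param settle noise-only settling period before encoding (ms)
#' @param delay_period delay between encoding and test (ms)
#' @param cue_spacing onset-to-onset spacing of successive cues (ms)
#' @param noise_per_generator logical flag recording that background rates
#'   apply to each generator of the pair rather than to their sum
#' @export
stimulation_params <- function(r_bg_enc = 650, r_bg_rec = 450,
                               r_bg_basket = 75, g_bg = 1.5, t_stim = 250,
                               r_stim = 500, isi = 500, t_cue = 50,
                               r_cue = 400, g_stim = 1.5, settle = 500,
                               delay_period = 1000, cue_spacing = 500,
                               noise_per_generator = TRUE) {
  if (any(c(r_bg_enc, r_bg_rec, r_bg_basket, r_stim, r_cue) < 0))
    stop("rates must be non-negative")
  structure(list(r_bg_enc = r_bg_enc, r_bg_rec = r_bg_rec,
                 r_bg_basket = r_bg_basket, g_bg = g_bg, t_stim = t_stim,
                 r_stim = r_stim, isi = isi, t_cue = t_cue, r_cue = r_cue,
                 g_stim = g_stim, settle = settle,
                 delay_period = delay_period, cue_spacing = cue_spacing,
                 noise_per_generator = isTRUE(noise_per_generator)),
            class = "semnet_stimulation_params")
}

#' Attractor-activation detector parameters
#'
#' Exponential moving average of a pattern-selective population's firing
#' rate, thresholded with hysteresis: activations count as terminated only
#' if the rate does not re-cross the threshold within the guard window, and
#' events shorter than `min_duration` are discarded.
#'
#' @param tau EMA filter time constant (ms)
#' @param delta_t sampling interval (ms)
#' @param n_pop size of the pattern-selective population (cells)
#' @param r_th detection threshold (Hz)
#' @param min_duration minimal supra-threshold duration of an event (ms)
#' @param guard offset re-cross guard window (ms)
#' @export
ema_params <- function(tau = 40, delta_t = 1, n_pop = 30, r_th = 10,
                       min_duration = 40, guard = 40) {
  if (delta_t >= tau) stop("delta_t must be smaller than tau")
  if (r_th <= 0) stop("r_th must be positive")
  structure(list(tau = tau, delta_t = delta_t, n_pop = n_pop, r_th = r_th,
                 min_duration = min_duration, guard = guard),
            class = "semnet_ema_params")
}

#' Simulation integration parameters
#'
#' Forward Euler integration at `dt`; a spike is registered when the
#' membrane potential reaches `spike_ceiling` (the AdEx exponential term
#' diverges, so any ceiling well above the threshold gives equivalent
#' timing).
#'
#' @param dt integration step (ms)
#' @param spike_ceiling numeric spike-detection ceiling (mV)
#' @export
sim_params <- function(dt = 0.1, spike_ceiling = 0) {
  if (dt <= 0) stop("dt must be positive")
  structure(list(dt = dt, spike_ceiling = spike_ceiling),
            class = "semnet_sim_params")
}

#' Bundle of all model parameters with table defaults
#'
#' @param ... named overrides: any of `neuron`, `basket`, `receptor`, `stp`,
#'   `bcpnn`, `stdp`, `layout`, `connectivity`, `stimulation`, `ema`, `sim`
#' @return list of parameter objects
#' @export
default_config <- function(...) {
  cfg <- list(neuron = neuron_params(), basket = basket_params(),
              receptor = receptor_params(), stp = stp_params(),
              bcpnn = bcpnn_params(), stdp = stdp_params(),
              layout = layout_params(), connectivity = connectivity_params(),
              stimulation = stimulation_params(), ema = ema_params(),
              sim = sim_params())
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  cfg
}
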