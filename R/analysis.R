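# Attractor-activation detection, recall scoring and the electrophysiology
# measurement harness.

#' Exponential moving average of a population firing rate
#'
#' Leaky-integrator estimate of the mean per-neuron rate of a
#' pattern-selective population, sampled every `delta_t`:
#' `e_t = (1 - delta_t/tau) e_{t-delta_t} + n_t / (n_pop * tau)`
#' with `n_t` the population spike count in the bin and `tau` in seconds for
#' a rate in Hz, so a constant per-neuron rate `f` yields steady state `f`.
#' The `literal` variant replaces the decay factor by `delta_t/tau`
#' (provided for comparison only; it cannot implement a 40-ms EMA and is not
#' used by the detector).
#'
#' @param spike_times spike times (ms)
#' @param spike_ids neuron ids aligned with `spike_times`
#' @param cells ids of the population (its size, not `params$n_pop`, is used
#'   for normalisation when they differ)
#' @param t_end end of the series (ms)
#' @param params see [ema_params()]
#' @param literal use the literal recursion (see Details)
#' @return data.frame with `time` (ms) and `rate` (Hz)
#' @export
ema_rate <- function(spike_times, spike_ids, cells, t_end,
                     params = ema_params(), literal = FALSE) {
  if (length(cells) == 0) stop("population must be non-empty")
  dT <- params$delta_t
  keep <- spike_ids %in% cells
  st <- spike_times[keep]
  n_bins <- ceiling(t_end / dT)
  counts <- tabulate(pmin(n_bins, floor(st / dT) + 1L), nbins = n_bins)
  tau_s <- params$tau / 1000
  npop <- length(cells)
  decay <- if (literal) dT / params$tau else 1 - dT / params$tau
  e <- as.numeric(filter(counts / (npop * tau_s), decay,
                         method = "recursive", init = 0))
  data.frame(time = seq_len(n_bins) * dT, rate = e)
}

#' Detect attractor activation events from a rate series
#'
#' Threshold crossings at `r_th` with hysteresis: sub-threshold dips shorter
#' than the guard window do not terminate an event, and events shorter than
#' `min_duration` are discarded.
#'
#' @param rate data.frame from [ema_rate()] or numeric rate vector
#' @param params see [ema_params()]
#' @param delta_t sampling interval when `rate` is a bare vector (ms)
#' @return data.frame with `onset`, `offset`, `duration` (ms), `peak` (Hz)
#' @export
detect_events <- function(rate, params = ema_params(),
                          delta_t = params$delta_t) {
  if (is.data.frame(rate)) {
    times <- rate$time
    r <- rate$rate
  } else {
    r <- as.numeric(rate)
    times <- seq_along(r) * delta_t
  }
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      duration = numeric(), peak = numeric())
  above <- r >= params$r_th
  if (!any(above)) return(empty)
  dd <- diff(c(0L, as.integer(above), 0L))
  starts <- which(dd == 1)
  ends <- which(dd == -1) - 1L
  # bridge sub-threshold gaps shorter than the re-cross guard
  if (length(starts) > 1) {
    gap <- times[starts[-1]] - times[ends[-length(ends)] + 1L]
    merge_prev <- gap < params$guard
    keep_s <- c(TRUE, !merge_prev)
    grp <- cumsum(keep_s)
    starts <- starts[keep_s]
    ends <- vapply(split(ends, grp), max, numeric(1))
  }
  onset <- times[starts]
  offset <- times[ends] + delta_t
  dur <- offset - onset
  peak <- mapply(function(s, e) max(r[s:e]), starts, ends)
  out <- data.frame(onset = onset, offset = offset, duration = dur,
                    peak = peak)
  out[out$duration >= params$min_duration, , drop = FALSE]
}

#' Score a cued-recall outcome
#'
#' For an item cue: an item-pattern activation accompanied by the activation
#' of any associated context is a remember-like outcome; item activation
#' alone is know-like (item recognition without episodic context); neither
#' is a miss.  The logic is symmetric for context cues, with the associated
#' item as the recollection target.
#'
#' @param events data.frame of detected events with columns `network`,
#'   `pattern`, `onset` (from [run_trial()] or assembled manually)
#' @param cue list with `network`, `pattern`, `window` (c(t0, t1) in ms)
#' @param association_map data.frame with `item`, `context`
#' @return list with `outcome` ("remember", "know" or "miss"),
#'   `cue_active`, and `recalled` (activated associated patterns of the
#'   opposite network)
#' @export
score_recall <- function(events, cue, association_map) {
  if (cue$network == "Item") {
    if (!cue$pattern %in% association_map$item) stop("unknown item cue")
    assoc <- association_map$context[association_map$item == cue$pattern]
    other <- "Context"
  } else {
    if (!cue$pattern %in% association_map$context)
      stop("unknown context cue")
    assoc <- association_map$item[association_map$context == cue$pattern]
    other <- "Item"
  }
  w <- cue$window
  inwin <- function(net, pat) {
    any(events$network == net & events$pattern %in% pat &
          events$onset >= w[1] & events$onset < w[2])
  }
  cue_active <- inwin(cue$network, cue$pattern)
  recalled <- unique(events$pattern[
    events$network == other & events$pattern %in% assoc &
      events$onset >= w[1] & events$onset < w[2]])
  outcome <- if (cue_active && length(recalled) > 0) "remember"
  else if (cue_active) "know" else "miss"
  list(outcome = outcome, cue_active = cue_active, recalled = recalled)
}

#' Measure a postsynaptic potential
#'
#' Holds the postsynaptic cell at `holding` with constant current, delivers
#' a single presynaptic spike through the connection's conductance
#' components, and returns the signed peak deflection.  By default the
#' first-spike short-term plasticity factor (`u+ x- = U` from rest) scales
#' glutamatergic conductances, matching a paired recording from silence;
#' `stp = "bare"` reports the unscaled conductance deflection.
#'
#' @param net a `semnet_network`
#' @param pre,post neuron ids; alternatively pass `synapses` indices
#' @param synapses row indices into the network synapse table
#' @param holding holding potential (mV); defaults to the resting potential
#' @param stp "first_spike" or "bare"
#' @param weights optional list with `wA`, `wN` vectors (nS, signed) that
#'   override the stored conductances of the selected synapses (used for
#'   post-encoding plastic weights; negative components are delivered at the
#'   GABA reversal)
#' @return data.frame with `synapse`, `pre`, `post`, `connected`, `psp` (mV;
#'   NA for an unconnected pair)
#' @export
measure_psp <- function(net, pre = NULL, post = NULL, synapses = NULL,
                        holding = net$params$neuron[["E_L"]],
                        stp = c("first_spike", "bare"), weights = NULL) {
  stp <- match.arg(stp)
  if (is.null(synapses)) {
    if (is.null(pre) || is.null(post)) stop("give pre/post or synapses")
    synapses <- which(net$synapses$pre == pre & net$synapses$post == post)
    if (length(synapses) == 0)
      return(data.frame(synapse = NA_integer_, pre = pre, post = post,
                        connected = FALSE, psp = NA_real_))
  }
  syn <- net$synapses[synapses, , drop = FALSE]
  p <- net$params
  tau <- p$receptor$tau_syn
  Er <- p$receptor$E_rev
  f <- if (stp == "first_spike") p$stp$U else 1
  psp <- vapply(seq_len(nrow(syn)), function(k) {
    wA <- if (!is.null(weights)) weights$wA[k] else syn$wA[k]
    wN <- if (!is.null(weights)) weights$wN[k] else syn$wN[k]
    wG <- if (!is.null(weights)) 0 else syn$wG[k]
    fk <- if (syn$stp[k] || !is.null(weights)) f else 1
    comp <- rbind(
      if (wA > 0) c(wA * fk, tau[["AMPA"]], Er[["AMPA"]]),
      if (wA < 0) c(-wA * fk, tau[["GABA"]], Er[["GABA"]]),
      if (wN > 0) c(wN * fk, tau[["NMDA"]], Er[["NMDA"]]),
      if (wN < 0) c(-wN * fk, tau[["GABA"]], Er[["GABA"]]),
      if (wG > 0) c(wG, tau[["GABA"]], Er[["GABA"]]))
    if (is.null(comp)) return(0)
    .engine_psp_peak(unclass(p$neuron), holding, comp, 0.01, 300)
  }, numeric(1))
  data.frame(synapse = synapses, pre = syn$pre, post = syn$post,
             connected = TRUE, psp = psp)
}

#' Sample the EPSP distribution of a synapse class
#'
#' @param net a preloaded `semnet_network`
#' @param class one of "rec_exc_within", "rec_exc_cross", "assoc"
#' @param n_sample number of connections to sample
#' @param seed sampling seed
#' @inheritParams measure_psp
#' @return data.frame as [measure_psp()]
#' @export
psp_distribution <- function(net, class = "rec_exc_within", n_sample = 100,
                             seed = 1, holding = net$params$neuron[["E_L"]],
                             stp = c("first_spike", "bare"),
                             weights = NULL) {
  within <- net$neurons$hc[net$synapses$pre] ==
    net$neurons$hc[net$synapses$post]
  idx <- switch(class,
    rec_exc_within = which(net$synapses$class == "rec_exc" & within),
    rec_exc_cross = which(net$synapses$class == "rec_exc" & !within),
    assoc = which(net$synapses$class == "assoc"),
    stop("unknown synapse class"))
  set.seed(seed)
  take <- sample(idx, min(n_sample, length(idx)))
  if (!is.null(weights)) {
    pl <- which(net$synapses$plastic)
    pos <- match(take, pl)
    weights <- list(wA = weights$wA[pos], wN = weights$wN[pos])
  }
  measure_psp(net, synapses = take, holding = holding,
              stp = match.arg(stp), weights = weights)
}

#' Summarize plastic weight, bias and recall statistics across trials
#'
#' Produces per-association-count summaries of the associative weight
#' distributions (AMPA and NMDA components separately, per direction), and
#' of the intrinsic excitability (bias) currents of item and context cells,
#' from post-encoding snapshots.
#'
#' @param trials list of `semnet_trial` results
#' @param snapshot which snapshot to summarise ("post_encoding" or "end")
#' @return list of data.frames `weights` and `bias` (empty for no trials)
#' @export
summarize_distributions <- function(trials, snapshot = "post_encoding") {
  if (length(trials) == 0)
    return(list(weights = data.frame(), bias = data.frame()))
  wlist <- list(); blist <- list()
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    map <- tr$association_map
    assoc_n <- table(map$item)
    syn <- tr$plastic_synapses
    snap <- tr$snapshots[[snapshot]]
    pairing <- paste(syn$item_pattern, syn$context_pattern) %in%
      paste(map$item, map$context)
    sel <- which(pairing)
    if (length(sel)) {
      wlist[[length(wlist) + 1]] <- data.frame(
        trial = ti, direction = syn$direction[sel],
        assoc = as.integer(assoc_n[as.character(syn$item_pattern[sel])]),
        item = syn$item_pattern[sel], context = syn$context_pattern[sel],
        wA = snap$wA[sel], wN = snap$wN[sel])
    }
    nn <- tr$neurons
    pyr <- nn$type == "pyr"
    item_assoc <- rep(NA_integer_, nrow(nn))
    it <- pyr & nn$network == "Item" & nn$pattern %in% map$item
    item_assoc[it] <- as.integer(assoc_n[as.character(nn$pattern[it])])
    cx <- pyr & nn$network == "Context" & nn$pattern %in% map$context
    item_assoc[cx] <- as.integer(assoc_n[as.character(
      map$item[match(nn$pattern[cx], map$context)])])
    keep <- it | cx
    blist[[length(blist) + 1]] <- data.frame(
      trial = ti, network = nn$network[keep], pattern = nn$pattern[keep],
      assoc = item_assoc[keep], bias = snap$bias[nn$id[keep]])
  }
  list(weights = do.call(rbind, wlist), bias = do.call(rbind, blist))
}
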