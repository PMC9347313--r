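# Reduced seven-neuron microcircuit with continuous weight tracking,
# sharing all kernel code with the full network model.

#' Microcircuit training protocol
#'
#' Two item neurons (ids 1-2) form two and three context associations
#' respectively (context neurons 3-4 and 5-7).  During training each pair is
#' stimulated to fire at `rate` for `epoch_s` seconds in sequential epochs;
#' a final readout spike is delivered to the item neurons at `readout_s`.
#' The tracked synapses are item1 -> context3 (two-association case) and
#' item2 -> context5 (three-association case); the remaining pairings are
#' simulated but only reported on request.
#'
#' @param rate training firing rate (Hz)
#' @param epoch_s epoch duration (s)
#' @param readout_s readout spike time (s)
#' @param t_total_s total simulated time (s)
#' @return list describing the protocol
#' @export
micro_protocol <- function(rate = 20, epoch_s = 2, readout_s = 11,
                           t_total_s = 12) {
  pairs <- data.frame(item = c(2, 1, 2, 1, 2), context = c(5, 3, 6, 4, 7),
                      onset_s = c(0, 2, 4, 6, 8))
  pairs$end_s <- pairs$onset_s + epoch_s
  if (readout_s < max(pairs$end_s))
    stop("readout must follow all training epochs")
  list(items = 1:2, contexts = 3:7,
       association_map = data.frame(item = c(1, 1, 2, 2, 2),
                                    context = c(3, 4, 5, 6, 7)),
       pairs = pairs, rate = rate, epoch_s = epoch_s,
       readout_s = readout_s, t_total_s = t_total_s,
       tracked = data.frame(pre = c(1, 2), post = c(3, 5)))
}

# synapse table of the microcircuit: plastic associative synapses in both
# directions for every item-context pairing
.micro_synapses <- function(protocol, t_min = 1.5) {
  am <- protocol$association_map
  data.frame(pre = c(am$item, am$context), post = c(am$context, am$item),
             class = "assoc", delay = t_min, plastic = TRUE, stp = TRUE,
             wA = 0, wN = 0, wG = 0)
}

#' Run the reduced microcircuit
#'
#' Trains the item-context pairings by supra-threshold periodic current
#' injection producing deterministic firing at the protocol rate, under the
#' chosen learning rule with plasticity parameters identical to the full
#' model, and records the tracked synaptic weights every millisecond.
#'
#' @param protocol see [micro_protocol()]
#' @param rule "bcpnn" or "stdp"
#' @param seed simulation seed (the default protocol is deterministic;
#'   the seed only matters with Poisson stimulation)
#' @param config model parameters, see [default_config()]
#' @param poisson_drive use Poisson conductance input at a matched rate
#'   instead of deterministic current pulses
#' @return object of class `semnet_micro` with `trajectories` (data.frame
#'   time_s, synapse, wA, wN), `traces` (per-ms BCPNN trace recordings),
#'   `raster` and the protocol
#' @export
run_microcircuit <- function(protocol = micro_protocol(),
                             rule = c("bcpnn", "stdp"), seed = 1,
                             config = default_config(),
                             poisson_drive = FALSE) {
  rule <- match.arg(rule)
  syn <- .micro_synapses(protocol, config$connectivity$t_min_syn)
  n <- max(protocol$contexts)
  group <- rep(0L, n)
  t_total <- protocol$t_total_s * 1000
  period <- 1000 / protocol$rate

  currents <- list(); stim <- list()
  for (k in seq_len(nrow(protocol$pairs))) {
    pr <- protocol$pairs[k, ]
    targets <- c(pr$item, pr$context)
    if (poisson_drive) {
      stim[[length(stim) + 1]] <- list(
        start = pr$onset_s * 1000, end = pr$end_s * 1000,
        rate = 50 * protocol$rate, g = 1.5, targets = targets)
    } else {
      currents[[length(currents) + 1]] <- list(
        start = pr$onset_s * 1000, end = pr$end_s * 1000, amp = 6000,
        period = period, width = 4, targets = targets)
    }
  }
  # readout spike, delivered to the presynaptic (item) neurons
  currents[[length(currents) + 1]] <- list(
    start = protocol$readout_s * 1000, end = protocol$readout_s * 1000 + 4,
    amp = 6000, period = 0, width = 0, targets = protocol$items)

  tracked <- vapply(seq_len(nrow(protocol$tracked)), function(i)
    which(syn$pre == protocol$tracked$pre[i] &
            syn$post == protocol$tracked$post[i])[1], integer(1))

  out <- .simulate(group, config, syn, rule, t_total,
                   noise = data.frame(t = 0, rate_pyr = 0, rate_basket = 0),
                   stim = stim, currents = currents,
                   kappa_default = config$bcpnn$kappa, tracked = tracked,
                   traced = if (rule == "bcpnn") tracked else integer(),
                   raster = TRUE, interval_ms = 1, seed = seed)

  n_rec <- length(out$rec_time)
  lab <- paste0(protocol$tracked$pre, "->", protocol$tracked$post)
  traj <- do.call(rbind, lapply(seq_along(tracked), function(j)
    data.frame(time_s = out$rec_time / 1000, synapse = lab[j],
               wA = out$tracked_w[, 2 * j - 1],
               wN = out$tracked_w[, 2 * j])))
  traces <- NULL
  if (rule == "bcpnn") {
    traces <- do.call(rbind, lapply(seq_along(tracked), function(j) {
      m <- out$traced[, (8 * (j - 1) + 1):(8 * j), drop = FALSE]
      data.frame(time_s = out$rec_time / 1000, synapse = lab[j],
                 Z_i = m[, 3], Z_j = m[, 4], P_i = m[, 5], P_j = m[, 6],
                 P_ij = m[, 7], w = m[, 8])
    }))
  }
  structure(list(trajectories = traj, traces = traces,
                 raster = data.frame(time = out$spike_t,
                                     neuron = out$spike_id),
                 protocol = protocol, rule = rule,
                 final_state = out$final_state,
                 synapses = syn, tracked = tracked),
            class = "semnet_micro")
}

#' @export
print.semnet_micro <- function(x, ...) {
  fin <- final_micro_weights(x)
  cat(sprintf("semnet microcircuit (%s rule)\n", x$rule))
  print(fin, row.names = FALSE)
  invisible(x)
}

#' Final tracked weights at the readout spike
#'
#' @param micro a `semnet_micro` result
#' @return data.frame with synapse labels, association count and final
#'   NMDA/AMPA weights (nS) measured just after the readout time
#' @export
final_micro_weights <- function(micro) {
  tr <- micro$trajectories
  t_read <- micro$protocol$readout_s
  out <- do.call(rbind, lapply(split(tr, tr$synapse), function(d) {
    k <- which.min(abs(d$time_s - (t_read + 0.5)))
    data.frame(synapse = d$synapse[1], wA = d$wA[k], wN = d$wN[k])
  }))
  am <- micro$protocol$association_map
  pre <- as.integer(sub("->.*", "", out$synapse))
  out$assoc <- vapply(pre, function(i) sum(am$item == i), integer(1))
  rownames(out) <- NULL
  out[, c("synapse", "assoc", "wA", "wN")]
}

#' Inspect BCPNN traces of a tracked microcircuit synapse
#'
#' @param micro a `semnet_micro` run with the BCPNN rule
#' @param synapse label such as "1->3"
#' @param t time in seconds
#' @return one-row data.frame with Z and P (NMDA-bank) traces and the weight
#' @export
trace_inspect <- function(micro, synapse = "1->3", t) {
  if (is.null(micro$traces)) stop("traces are recorded for the BCPNN rule")
  d <- micro$traces[micro$traces$synapse == synapse, , drop = FALSE]
  if (nrow(d) == 0) stop("unknown synapse label")
  if (t < min(d$time_s) || t > max(d$time_s))
    stop("t outside the simulated interval")
  d[which.min(abs(d$time_s - t)), , drop = FALSE]
}
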