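# Two-network modular architecture: hypercolumn/minicolumn geometry, cell
# populations, Bernoulli connectivity, distance-dependent delays, preloaded
# attractor weights and basket-cell winner-take-all wiring.

hc_grid <- function(n_hc, patch_size) {
  nx <- max(1, round(sqrt(n_hc * patch_size[1] / patch_size[2])))
  ny <- ceiling(n_hc / nx)
  ix <- ((seq_len(n_hc) - 1) %% nx) + 1
  iy <- ((seq_len(n_hc) - 1) %/% nx) + 1
  data.frame(hc = seq_len(n_hc),
             x = (ix - 0.5) * patch_size[1] / nx,
             y = (iy - 0.5) * patch_size[2] / ny)
}

# Bernoulli-sample ordered pairs from pre_ids x post_ids at probability p.
# With exclude_self, diagonal pairs (same index in a shared id set) are
# excluded from the sample space.
sample_pairs <- function(pre_ids, post_ids, p, exclude_self = FALSE) {
  n1 <- length(pre_ids); n2 <- length(post_ids)
  if (exclude_self) {
    stopifnot(n1 == n2)
    npairs <- n1 * (n2 - 1)
    k <- rbinom(1, npairs, p)
    if (k == 0) return(list(pre = integer(), post = integer()))
    idx <- sample.int(npairs, k)
    i <- (idx - 1) %/% (n2 - 1) + 1
    joff <- (idx - 1) %% (n2 - 1) + 1
    j <- joff + (joff >= i)
  } else {
    npairs <- n1 * n2
    k <- rbinom(1, npairs, p)
    if (k == 0) return(list(pre = integer(), post = integer()))
    idx <- sample.int(npairs, k)
    i <- (idx - 1) %/% n2 + 1
    j <- (idx - 1) %% n2 + 1
  }
  list(pre = pre_ids[i], post = post_ids[j])
}

#' Sample axonal conduction delays
#'
#' Delays are drawn from a normal distribution with mean
#' `distance / speed + t_min` and relative SD `jitter_rel` of the mean,
#' truncated below at `t_min` (normal samples can go negative; the minimal
#' synaptic delay reflects unmodelled transmission steps and always
#' applies).
#'
#' @param distance Euclidean distance (mm), vectorised
#' @param speed conduction speed (m/s)
#' @param jitter_rel relative SD of the delay distribution
#' @param t_min minimal synaptic delay (ms)
#' @return delays in ms, same length as `distance`
#' @export
sample_delay <- function(distance, speed, jitter_rel = 0.3, t_min = 1.5) {
  if (any(distance < 0)) stop("distance must be non-negative")
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("speed must be positive")
  m <- distance / speed + t_min
  pmax(t_min, rnorm(length(m), mean = m, sd = jitter_rel * m))
}

#' Default item-context association map
#'
#' Four items forming 3, 2, 1 and 4 context associations respectively
#' (10 distinct contexts, each used exactly once), mirroring the default
#' episodic task: item 3 is encoded in a single context and item 4 across
#' four different contexts.
#'
#' @param layout see [layout_params()]
#' @return data.frame with columns `item` and `context`
#' @export
default_association_map <- function(layout = layout_params()) {
  map <- data.frame(item = c(1, 1, 1, 2, 2, 3, 4, 4, 4, 4),
                    context = c(1, 5, 10, 2, 6, 3, 4, 7, 8, 9))
  stopifnot(max(map$item) <= layout$n_items,
            max(map$context) <= layout$n_contexts)
  map
}

#' Build the two-network architecture
#'
#' Instantiates the Item and Context networks on their hypercolumn grids,
#' draws Bernoulli connectivity (within-HC pyramidal pairs at `cp_pp`,
#' cross-HC pairs at `cp_ppl`, internetwork associative pairs at `cp_ppa`,
#' pyramidal-basket loops at `cp_pb`/`cp_bp`) and samples distance-dependent
#' conduction delays (associative axons at the myelinated speed).  Pyramidal
#' pairs of the same memory pattern become attractor (excitatory) recurrent
#' synapses; pairs of competing minicolumns become the learned monosynaptic
#' inhibition class.  Recurrent weights are unset until
#' [preload_attractors()] is called; associative synapses are plastic and
#' start from the naive prior of the chosen learning rule.
#'
#' @param layout see [layout_params()]
#' @param conn see [connectivity_params()]
#' @param seed RNG seed; the same seed reproduces the identical network
#' @param config model parameter bundle, see [default_config()]
#' @param association_map item-context pairings, see
#'   [default_association_map()]
#' @return object of class `semnet_network`
#' @export
build_network <- function(layout = layout_params(),
                          conn = connectivity_params(), seed = 1,
                          config = default_config(),
                          association_map = default_association_map(layout)) {
  set.seed(seed)
  n_mc <- layout$n_mc_per_hc
  npyr_mc <- layout$pyr_per_mc
  nba_mc <- layout$basket_per_mc

  grid <- hc_grid(layout$n_hc, layout$patch_size)
  neurons <- do.call(rbind, lapply(1:2, function(nt) {
    per_hc <- n_mc * (npyr_mc + nba_mc)
    hc <- rep(grid$hc, each = per_hc)
    mc <- rep(rep(seq_len(n_mc), each = npyr_mc + nba_mc), layout$n_hc)
    type <- rep(rep(c(rep("pyr", npyr_mc), rep("basket", nba_mc))), layout$n_hc * n_mc)
    data.frame(network = c("Item", "Context")[nt], hc = hc, mc = mc,
               type = type,
               x = grid$x[hc] + (nt - 1) * layout$internetwork_distance,
               y = grid$y[hc])
  }))
  neurons$id <- seq_len(nrow(neurons))
  # non-overlapping patterns: pattern p occupies minicolumn p in every HC
  neurons$pattern <- ifelse(neurons$type == "pyr", neurons$mc, NA)
  neurons <- neurons[, c("id", "network", "hc", "mc", "type", "pattern",
                         "x", "y")]

  is_pyr <- neurons$type == "pyr"
  acc <- list()
  add <- function(pre, post, class) {
    if (length(pre) == 0) return(invisible(NULL))
    acc[[length(acc) + 1]] <<- data.frame(pre = pre, post = post,
                                          class = class)
  }

  for (nt in c("Item", "Context")) {
    sel <- neurons$network == nt
    pyr <- neurons$id[sel & is_pyr]
    # within-HC pyramidal pairs at cp_pp
    for (h in seq_len(layout$n_hc)) {
      ph <- neurons$id[sel & is_pyr & neurons$hc == h]
      s <- sample_pairs(ph, ph, conn$cp_pp, exclude_self = TRUE)
      cls <- ifelse(neurons$mc[s$pre] == neurons$mc[s$post],
                    "rec_exc", "rec_inh")
      add(s$pre, s$post, cls)
      # basket loop, within HC
      ba <- neurons$id[sel & !is_pyr & neurons$hc == h]
      s <- sample_pairs(ph, ba, conn$cp_pb)
      add(s$pre, s$post, "pyr_ba")
      s <- sample_pairs(ba, ph, conn$cp_bp)
      add(s$pre, s$post, "ba_pyr")
    }
    # cross-HC pyramidal pairs at cp_ppl (drop same-HC draws: handled above)
    s <- sample_pairs(pyr, pyr, conn$cp_ppl)
    keep <- neurons$hc[s$pre] != neurons$hc[s$post]
    cls <- ifelse(neurons$pattern[s$pre] == neurons$pattern[s$post],
                  "rec_exc", "rec_inh")
    add(s$pre[keep], s$post[keep], cls[keep])
  }
  # associative internetwork projections (both directions), plastic
  it_pyr <- neurons$id[neurons$network == "Item" & is_pyr]
  cx_pyr <- neurons$id[neurons$network == "Context" & is_pyr]
  s <- sample_pairs(it_pyr, cx_pyr, conn$cp_ppa)
  add(s$pre, s$post, "assoc")
  s <- sample_pairs(cx_pyr, it_pyr, conn$cp_ppa)
  add(s$pre, s$post, "assoc")

  synapses <- do.call(rbind, acc)
  d <- sqrt((neurons$x[synapses$pre] - neurons$x[synapses$post])^2 +
              (neurons$y[synapses$pre] - neurons$y[synapses$post])^2)
  speed <- ifelse(synapses$class == "assoc", conn$speed_myel, conn$speed)
  synapses$delay <- sample_delay(d, speed, conn$delay_jitter, conn$t_min_syn)
  synapses$plastic <- synapses$class == "assoc"
  # short-term plasticity on all glutamatergic synapses; GABAergic
  # (basket->pyramidal) and the GABA-routed competing-MC weights are static
  synapses$stp <- synapses$class %in% c("rec_exc", "assoc", "pyr_ba")
  synapses$wA <- ifelse(synapses$class == "pyr_ba", conn$g_pb, 0)
  synapses$wN <- 0
  synapses$wG <- ifelse(synapses$class == "ba_pyr", abs(conn$g_bp), 0)

  pattern_book <- list(
    # pattern p -> selective MC per HC (identity mapping in both networks)
    mc_of_pattern = setNames(seq_len(n_mc), seq_len(n_mc)),
    association_map = association_map)

  structure(list(neurons = neurons, synapses = synapses,
                 pattern_book = pattern_book, layout = layout, conn = conn,
                 params = config, preload = NULL, kappa_overrides = list(),
                 seed = seed),
            class = "semnet_network")
}

#' @export
print.semnet_network <- function(x, ...) {
  n_pyr <- sum(x$neurons$type == "pyr")
  n_ba <- sum(x$neurons$type == "basket")
  cat("semnet two-network model\n")
  cat(sprintf("  %d HCs x %d MCs per network; %d pyramidal, %d basket cells\n",
              x$layout$n_hc, x$layout$n_mc_per_hc, n_pyr, n_ba))
  cat(sprintf("  %d synapses (%d plastic associative)\n",
              nrow(x$synapses), sum(x$synapses$plastic)))
  cat(sprintf("  attractors %s\n",
              if (is.null(x$preload)) "not preloaded"
              else sprintf("preloaded (conductance scale %.3f)",
                           x$preload$scale)))
  invisible(x)
}

#' Pyramidal cells of a memory pattern
#'
#' @param net a `semnet_network`
#' @param network "Item" or "Context"
#' @param pattern pattern id (minicolumn index)
#' @param hc optionally restrict to one hypercolumn
#' @return neuron ids
#' @export
pattern_cells <- function(net, network, pattern, hc = NULL) {
  sel <- net$neurons$network == network & net$neurons$type == "pyr" &
    net$neurons$pattern == pattern
  if (!is.null(hc)) sel <- sel & net$neurons$hc %in% hc
  net$neurons$id[sel & !is.na(net$neurons$pattern)]
}

#' Preload long-term attractor memories
#'
#' Assigns static recurrent weights representing well-consolidated memory
#' patterns: positive attractor projections among same-pattern pyramidal
#' cells (stronger within a hypercolumn than across), and negative weights
#' between competing minicolumns delivered at the GABA reversal (learned
#' monosynaptic rendering of disynaptic inhibition).  Weights are drawn in
#' log-odds model units and converted to conductance via the per-receptor
#' gains and a global scale, which is calibrated so that the mean within-HC
#' same-pattern EPSP (first presynaptic spike, measured at rest) matches
#' `target_epsp`.
#'
#' @param net a `semnet_network`
#' @param mean_within,sd_within within-HC attractor weight distribution
#'   (model units)
#' @param mean_cross,sd_cross cross-HC attractor weight distribution
#' @param mean_inh,sd_inh competing-minicolumn weight distribution (negative)
#' @param target_epsp calibration target for the mean within-HC EPSP (mV)
#' @param seed RNG seed for the weight draws
#' @return the network with recurrent weights and calibration info set
#' @export
preload_attractors <- function(net, mean_within = 2.15, sd_within = 0.55,
                               mean_cross = 2.05, sd_cross = 0.45,
                               mean_inh = -0.3, sd_inh = 0.12,
                               target_epsp = 0.45, seed = net$seed + 1) {
  stopifnot(inherits(net, "semnet_network"))
  if (sum(net$synapses$class %in% c("rec_exc", "rec_inh")) == 0)
    stop("network has no recurrent synapses to preload")
  if (nrow(net$pattern_book$association_map) == 0)
    stop("empty pattern book")
  set.seed(seed)
  syn <- net$synapses
  within <- net$neurons$hc[syn$pre] == net$neurons$hc[syn$post]
  exc <- syn$class == "rec_exc"
  inh <- syn$class == "rec_inh"
  units <- rep(0, nrow(syn))
  iw <- exc & within
  ic <- exc & !within
  units[iw] <- pmax(0.05, rnorm(sum(iw), mean_within, sd_within))
  units[ic] <- pmax(0.05, rnorm(sum(ic), mean_cross, sd_cross))
  units[inh] <- pmin(0, rnorm(sum(inh), mean_inh, sd_inh))

  scale <- calibrate_epsp_scale(net, mean_within, target_epsp)
  gain <- net$params$bcpnn$w_gain
  syn$units <- units
  syn$wA[exc] <- scale * gain[["AMPA"]] * units[exc]
  syn$wN[exc] <- scale * gain[["NMDA"]] * units[exc]
  syn$wG[inh] <- scale * (gain[["AMPA"]] + gain[["NMDA"]]) * abs(units[inh])
  net$synapses <- syn
  net$preload <- list(scale = scale, target_epsp = target_epsp,
                      mean_within = mean_within, mean_cross = mean_cross,
                      mean_inh = mean_inh)
  net
}

# Solve for the conductance scale that makes the mean within-HC attractor
# EPSP (single presynaptic spike from rest, first-spike STP factor applied)
# equal to the target, by fixed-point iteration on the simulated peak.
calibrate_epsp_scale <- function(net, mean_within, target_epsp) {
  p <- net$params
  U <- p$stp$U  # first spike from rest: u+ = U, x- = 1
  gain <- p$bcpnn$w_gain
  tau <- p$receptor$tau_syn
  Er <- p$receptor$E_rev
  scale <- 1
  for (rep in 1:4) {
    comp <- cbind(g = scale * U * mean_within * c(gain[["AMPA"]], gain[["NMDA"]]),
                  tau = c(tau[["AMPA"]], tau[["NMDA"]]),
                  E = c(Er[["AMPA"]], Er[["NMDA"]]))
    peak <- .engine_psp_peak(unclass(p$neuron), p$neuron[["E_L"]], comp,
                             0.01, 300)
    scale <- scale * target_epsp / peak
  }
  scale
}

#' Serialize a network connection table
#'
#' Writes the synapse table as tab-separated text (pre id, post id, class,
#' conductances, delay, plastic flag).
#'
#' @param net a `semnet_network`
#' @param path output file
#' @export
write_network <- function(net, path) {
  write.table(net$synapses[, c("pre", "post", "class", "wA", "wN", "wG",
                               "delay", "plastic")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
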