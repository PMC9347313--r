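# The episodic item-context task: stimulus schedules, trial simulation and
# multi-trial experiments.

#' Experiment configuration
#'
#' @param variant task variant: item-cued recall (contexts are the
#'   recollection target), context-cued recall, multi-cue (all contexts of
#'   the highest-variability item are cued sequentially),
#'   preferential-retention (one pairing encoded with boosted plasticity),
#'   or the STDP conditions (with or without synaptic augmentation)
#' @param rule learning rule for the associative projections; defaults to
#'   "stdp" for the STDP variants and "bcpnn" otherwise
#' @param n_trials number of independently seeded trials
#' @param association_map item-context pairings (default
#'   [default_association_map()])
#' @param shuffle shuffle the encoding order of the pairings per trial
#' @param boost_pair pairing (item, context) receiving kappa_boost in the
#'   preferential-retention variant
#' @param freeze_at_test freeze plasticity (kappa = 0) during the test phase
#' @param compensation stimulation rate/gain multipliers applied in the
#'   no-augmentation condition to restore comparable spiking activity
#' @param stimulation see [stimulation_params()]
#' @export
experiment_config <- function(variant = c("item-cued", "context-cued",
                                          "multi-cue",
                                          "preferential-retention", "stdp",
                                          "stdp-no-augmentation"),
                              rule = NULL, n_trials = 20,
                              association_map = NULL, shuffle = TRUE,
                              boost_pair = c(item = 1, context = 5),
                              freeze_at_test = FALSE,
                              compensation = c(rate = 1.3, gain = 1.3),
                              stimulation = stimulation_params()) {
  variant <- match.arg(variant)
  if (is.null(rule))
    rule <- if (startsWith(variant, "stdp")) "stdp" else "bcpnn"
  structure(list(variant = variant, rule = rule, n_trials = n_trials,
                 association_map = association_map, shuffle = shuffle,
                 boost_pair = boost_pair, freeze_at_test = freeze_at_test,
                 compensation = compensation, stimulation = stimulation),
            class = "semnet_experiment_config")
}

#' Build the stimulus schedule of one trial
#'
#' Encoding epochs drive each item pattern together with its paired context
#' pattern (250 ms at 500 Hz, interstimulus interval 500 ms), preceded by a
#' noise-only settling period; the test phase starts 1 s after encoding ends
#' and consists of brief 50-ms cues (400 Hz) of items or contexts depending
#' on the task variant.  Background noise switches from the encoding to the
#' recall rate at the start of the delay.
#'
#' @param config see [experiment_config()]
#' @param net a `semnet_network` (for the association map default)
#' @param seed RNG seed for the encoding order shuffle
#' @return object of class `semnet_schedule`
#' @export
build_schedule <- function(config, net, seed = 1) {
  st <- config$stimulation
  map <- config$association_map %||% net$pattern_book$association_map
  if (nrow(map) > 0 && anyDuplicated(map$context))
    stop("each context may be used at most once")
  if (nrow(map) > 0 &&
      (max(map$item) > net$layout$n_mc_per_hc ||
       max(map$context) > net$layout$n_mc_per_hc))
    stop("association map refers to unknown patterns")
  set.seed(seed)
  ord <- seq_len(nrow(map))
  if (isTRUE(config$shuffle) && nrow(map) > 1) ord <- sample(ord)
  map <- map[ord, , drop = FALSE]

  rate_mult <- 1; gain_mult <- 1
  if (config$variant == "stdp-no-augmentation") {
    rate_mult <- config$compensation[["rate"]]
    gain_mult <- config$compensation[["gain"]]
  }

  n_enc <- nrow(map)
  enc_onset <- st$settle + (seq_len(n_enc) - 1) * (st$t_stim + st$isi)
  t_enc_end <- if (n_enc > 0) enc_onset[n_enc] + st$t_stim else st$settle
  t_test <- t_enc_end + st$delay_period

  encoding <- if (n_enc > 0) data.frame(
    phase = "encoding", onset = enc_onset, duration = st$t_stim,
    rate = st$r_stim * rate_mult, g = st$g_stim * gain_mult,
    item = map$item, context = map$context) else
    data.frame(phase = character(), onset = numeric(), duration = numeric(),
               rate = numeric(), g = numeric(), item = integer(),
               context = integer())

  cues <- data.frame(network = character(), pattern = integer(),
                     onset = numeric(), group = integer(),
                     assoc = integer())
  if (n_enc > 0) {
    assoc_n <- table(map$item)
    if (config$variant %in% c("item-cued", "preferential-retention", "stdp",
                              "stdp-no-augmentation")) {
      items <- sort(unique(map$item))
      cues <- data.frame(network = "Item", pattern = items,
                         group = seq_along(items),
                         assoc = as.integer(assoc_n[as.character(items)]))
    } else if (config$variant == "context-cued") {
      ctx <- sort(unique(map$context))
      cues <- data.frame(network = "Context", pattern = ctx,
                         group = seq_along(ctx),
                         assoc = as.integer(assoc_n[as.character(
                           map$item[match(ctx, map$context)])]))
    } else if (config$variant == "multi-cue") {
      # contexts of lower-variability items individually; the contexts of
      # the maximal-association item back-to-back as one scored group
      an <- as.integer(assoc_n[as.character(map$item)])
      maxi <- as.integer(names(assoc_n))[which.max(assoc_n)]
      single <- sort(map$context[map$item != maxi])
      multi <- sort(map$context[map$item == maxi])
      ctx <- c(single, multi)
      grp <- c(seq_along(single), rep(length(single) + 1L, length(multi)))
      cues <- data.frame(network = "Context", pattern = ctx, group = grp,
                         assoc = as.integer(assoc_n[as.character(
                           map$item[match(ctx, map$context)])]))
    }
    # cue order is shuffled with the trial seed (it is not part of the
    # protocol); multi-cue groups stay contiguous
    if (isTRUE(config$shuffle) && nrow(cues) > 1) {
      gord <- sample(unique(cues$group))
      cues <- cues[order(match(cues$group, gord)), , drop = FALSE]
    }
    cues$onset <- t_test + (seq_len(nrow(cues)) - 1) * st$cue_spacing
    cues$duration <- st$t_cue
    cues$rate <- st$r_cue * rate_mult
    cues$g <- st$g_stim * gain_mult
  }
  t_end <- if (nrow(cues) > 0) max(cues$onset) + st$cue_spacing else
    t_test + st$cue_spacing

  kappa_epochs <- list()
  if (config$variant == "preferential-retention" && n_enc > 0) {
    bp <- config$boost_pair
    k <- which(map$item == bp[["item"]] & map$context == bp[["context"]])
    if (length(k) != 1)
      stop("boost_pair is not a pairing of the association map")
    kappa_epochs <- list(list(start = enc_onset[k],
                              end = enc_onset[k] + st$t_stim,
                              kappa = net$params$bcpnn$kappa_boost,
                              pair = c(item = unname(bp[["item"]]),
                                       context = unname(bp[["context"]]))))
  }

  # elevated (encoding-level) background accompanies the stimulation
  # epochs; unstimulated periods (settling, interstimulus gaps, delay,
  # test) run at the recall-level background.  This keeps the network out
  # of the free-recall regime of spontaneous reactivations between epochs.
  noise <- data.frame(t = 0, rate_pyr = st$r_bg_rec,
                      rate_basket = st$r_bg_basket)
  for (k in seq_len(n_enc)) {
    noise <- rbind(noise,
      data.frame(t = enc_onset[k], rate_pyr = st$r_bg_enc,
                 rate_basket = st$r_bg_basket),
      data.frame(t = enc_onset[k] + st$t_stim, rate_pyr = st$r_bg_rec,
                 rate_basket = st$r_bg_basket))
  }
  structure(list(
    encoding = encoding, cues = cues, association_map = map,
    noise = noise,
    kappa_epochs = kappa_epochs,
    augmentation = config$variant != "stdp-no-augmentation",
    freeze_at_test = isTRUE(config$freeze_at_test),
    t_enc_end = t_enc_end, t_test = t_test, t_end = t_end,
    stimulation = st, variant = config$variant, seed = seed),
    class = "semnet_schedule")
}

#' @export
print.semnet_schedule <- function(x, ...) {
  cat(sprintf("semnet %s schedule: %d encoding epochs, %d cues, %.1f s\n",
              x$variant, nrow(x$encoding), nrow(x$cues), x$t_end / 1000))
  invisible(x)
}

# indices of associative synapses linking the cells of one pairing
.pairing_synapses <- function(net, item, context) {
  syn <- net$synapses
  nn <- net$neurons
  it <- which(syn$class == "assoc" &
                nn$network[syn$pre] == "Item" &
                nn$pattern[syn$pre] == item &
                nn$pattern[syn$post] == context)
  ci <- which(syn$class == "assoc" &
                nn$network[syn$pre] == "Context" &
                nn$pattern[syn$pre] == context &
                nn$pattern[syn$post] == item)
  c(it, ci)
}

#' Run one trial of the episodic memory task
#'
#' Full clock-driven simulation through settling, encoding, delay and cued
#' recall, followed by attractor-event detection and recall scoring.
#' Bit-reproducible for a fixed seed.
#'
#' @param net a preloaded `semnet_network`
#' @param schedule see [build_schedule()]
#' @param rule "bcpnn" or "stdp"
#' @param seed simulation seed
#' @param sample_hc hypercolumn whose minicolumns form the detector
#'   populations
#' @param raster keep the full spike raster in the result
#' @return object of class `semnet_trial`
#' @export
run_trial <- function(net, schedule, rule = c("bcpnn", "stdp"), seed = 1,
                      sample_hc = 1, raster = TRUE) {
  rule <- match.arg(rule)
  if (is.null(net$preload)) stop("preload attractors before running trials")
  nn <- net$neurons
  group <- as.integer(nn$type == "basket")

  stim <- list()
  for (k in seq_len(nrow(schedule$encoding))) {
    e <- schedule$encoding[k, ]
    stim[[length(stim) + 1]] <- list(
      start = e$onset, end = e$onset + e$duration, rate = e$rate, g = e$g,
      targets = c(pattern_cells(net, "Item", e$item),
                  pattern_cells(net, "Context", e$context)))
  }
  for (k in seq_len(nrow(schedule$cues))) {
    cu <- schedule$cues[k, ]
    stim[[length(stim) + 1]] <- list(
      start = cu$onset, end = cu$onset + cu$duration, rate = cu$rate,
      g = cu$g, targets = pattern_cells(net, cu$network, cu$pattern))
  }

  kappa_epochs <- lapply(schedule$kappa_epochs, function(e) {
    sidx <- .pairing_synapses(net, e$pair[["item"]], e$pair[["context"]])
    targets <- unique(net$synapses$post[sidx])
    list(start = e$start, end = e$end, kappa = e$kappa, synapses = sidx,
         neurons = targets)
  })
  for (ov in net$kappa_overrides) {
    kappa_epochs[[length(kappa_epochs) + 1]] <-
      list(start = 0, end = schedule$t_end, kappa = ov$kappa,
           synapses = ov$synapses, neurons = ov$neurons)
  }
  if (schedule$freeze_at_test) {
    kappa_epochs[[length(kappa_epochs) + 1]] <-
      list(start = schedule$t_test, end = schedule$t_end, kappa = 0,
           synapses = which(net$synapses$plastic),
           neurons = nn$id[nn$type == "pyr"])
  }

  # synapses start at the baseline-activity fixed point of the short-term
  # dynamics (see stp_baseline_state): the 5-s augmentation time constant
  # cannot be equilibrated by the brief settling period
  s0 <- stp_baseline_state(net$params$stp)
  nstp <- sum(net$synapses$stp)
  init_state <- list(stp_u = rep(s0$u, nstp), stp_x = rep(s0$x, nstp))

  out <- .simulate(group, net$params, net$synapses, rule,
                   t_total = schedule$t_end, noise = schedule$noise,
                   g_bg = schedule$stimulation$g_bg, stim = stim,
                   kappa_default = net$params$bcpnn$kappa,
                   kappa_epochs = kappa_epochs, init_state = init_state,
                   snapshots_ms = c(schedule$t_enc_end,
                                    schedule$t_end - net$params$sim$dt),
                   raster = TRUE, seed = seed,
                   augmentation = net$params$stp$augmentation &&
                     schedule$augmentation,
                   # pretrained network: bias traces start at the pattern
                   # prior (one selective MC in n_MC per HC), consistent
                   # with the preloaded attractor log-odds
                   bias_p0 = 1 / net$layout$n_mc_per_hc)
  if (any(!is.finite(out$final_state$V)))
    stop("numeric divergence: non-finite membrane state at end of trial")

  # attractor-event detection per pattern in both networks
  map <- schedule$association_map
  events <- list()
  emap <- net$params$ema
  for (network in c("Item", "Context")) {
    pats <- if (network == "Item") sort(unique(map$item)) else
      sort(unique(map$context))
    for (p in pats) {
      cells <- pattern_cells(net, network, p, hc = sample_hc)
      r <- ema_rate(out$spike_t, out$spike_id, cells, schedule$t_end, emap)
      ev <- detect_events(r, emap)
      if (nrow(ev) > 0)
        events[[length(events) + 1]] <-
          cbind(data.frame(network = network, pattern = p), ev)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(network = character(), pattern = integer(),
               onset = numeric(), offset = numeric(), duration = numeric(),
               peak = numeric())

  # score each cue group
  cues <- schedule$cues
  outcomes <- list()
  for (g in unique(cues$group)) {
    cg <- cues[cues$group == g, , drop = FALSE]
    window <- c(cg$onset[1],
                cg$onset[nrow(cg)] + schedule$stimulation$cue_spacing)
    sc <- score_recall(events,
                       list(network = cg$network[1],
                            pattern = cg$pattern[1], window = window),
                       map)
    # for a multi-cue group any of the cued patterns may carry the cue
    if (nrow(cg) > 1) {
      per <- lapply(seq_len(nrow(cg)), function(i)
        score_recall(events, list(network = cg$network[i],
                                  pattern = cg$pattern[i],
                                  window = window), map))
      cue_active <- any(vapply(per, `[[`, logical(1), "cue_active"))
      recalled <- unique(unlist(lapply(per, `[[`, "recalled")))
      outcome <- if (cue_active && length(recalled)) "remember"
      else if (cue_active) "know" else "miss"
      sc <- list(outcome = outcome, cue_active = cue_active,
                 recalled = recalled)
    }
    outcomes[[length(outcomes) + 1]] <- data.frame(
      group = g, network = cg$network[1],
      pattern = paste(cg$pattern, collapse = "+"),
      assoc = cg$assoc[1], outcome = sc$outcome,
      cue_active = sc$cue_active,
      recalled = paste(sc$recalled, collapse = "+"))
  }
  outcomes <- if (length(outcomes)) do.call(rbind, outcomes) else
    data.frame()

  plastic <- net$synapses[net$synapses$plastic, c("pre", "post")]
  pre_item <- nn$network[plastic$pre] == "Item"
  plastic$direction <- ifelse(pre_item, "item_to_context",
                              "context_to_item")
  plastic$item_pattern <- ifelse(pre_item, nn$pattern[plastic$pre],
                                 nn$pattern[plastic$post])
  plastic$context_pattern <- ifelse(pre_item, nn$pattern[plastic$post],
                                    nn$pattern[plastic$pre])
  snaps <- lapply(out$snapshots, function(s)
    list(wA = s$wA, wN = s$wN, bias = s$bias))
  names(snaps) <- c("post_encoding", "end")[seq_along(snaps)]

  structure(list(
    raster = if (raster) data.frame(time = out$spike_t,
                                    neuron = out$spike_id) else NULL,
    events = events, outcomes = outcomes, snapshots = snaps,
    final_state = out$final_state, plastic_synapses = plastic,
    neurons = nn, association_map = map, schedule = schedule, rule = rule,
    seed = seed), class = "semnet_trial")
}

#' @export
print.semnet_trial <- function(x, ...) {
  cat(sprintf("semnet trial (%s rule, seed %d): %d spikes, %d events\n",
              x$rule, x$seed,
              if (is.null(x$raster)) NA_integer_ else nrow(x$raster),
              nrow(x$events)))
  if (nrow(x$outcomes)) {
    cat("  cue outcomes:\n")
    print(x$outcomes[, c("network", "pattern", "assoc", "outcome",
                         "recalled")], row.names = FALSE)
  }
  invisible(x)
}

#' Enable or disable the synaptic augmentation pathway
#'
#' With augmentation disabled the utilization variable is pinned to `U` on
#' every spike, removing short-term facilitation while keeping depression.
#'
#' @param net a `semnet_network`
#' @param enabled logical
#' @export
toggle_augmentation <- function(net, enabled) {
  stopifnot(inherits(net, "semnet_network"))
  net$params$stp$augmentation <- isTRUE(enabled)
  net
}

#' Run a multi-trial experiment
#'
#' Builds an independently seeded network realisation and stimulus order
#' per trial, runs the task, and aggregates cued-recall performance per
#' association count (mean and Bernoulli SD across trials).
#'
#' @param config see [experiment_config()]
#' @param layout,conn network parameters
#' @param n_trials overrides `config$n_trials`
#' @param seed base seed; trial i uses `seed + 7919 * (i - 1)`
#' @param model_config full parameter bundle, see [default_config()]
#' @param keep_trials keep the individual trial objects (memory-heavy)
#' @return list with `recall` table, `weights` summary and optionally
#'   `trials`
#' @export
run_experiment <- function(config, layout = layout_params(),
                           conn = connectivity_params(),
                           n_trials = config$n_trials, seed = 1,
                           model_config = default_config(),
                           keep_trials = FALSE) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  trials <- vector("list", n_trials)
  rows <- list()
  for (i in seq_len(n_trials)) {
    si <- seed + 7919 * (i - 1)
    net <- build_network(layout, conn, seed = si, config = model_config)
    net <- preload_attractors(net)
    if (config$variant == "stdp-no-augmentation")
      net <- toggle_augmentation(net, FALSE)
    sched <- build_schedule(config, net, seed = si)
    tr <- run_trial(net, sched, rule = config$rule, seed = si,
                    raster = keep_trials)
    rows[[i]] <- cbind(trial = i, tr$outcomes)
    if (!keep_trials) tr$raster <- NULL
    trials[[i]] <- tr
  }
  oc <- do.call(rbind, rows)
  oc$success <- oc$outcome == "remember"
  agg <- aggregate(success ~ assoc, oc, mean)
  names(agg)[2] <- "recall"
  agg$sd <- sqrt(agg$recall * (1 - agg$recall))
  agg$n_trials <- n_trials
  sums <- summarize_distributions(trials)
  res <- list(recall = agg, outcomes = oc, weights = sums$weights,
              bias = sums$bias, config = config)
  if (keep_trials) res$trials <- trials
  res
}
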