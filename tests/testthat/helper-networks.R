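# Shared fixtures.  Expensive simulations are run once per test session and
# cached; every fixture is generated in code from a fixed seed.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small two-network model for structural and dynamical unit tests
tiny_layout <- function() layout_params(n_hc = 2)

reduced_layout <- function() layout_params(n_hc = 6)

tiny_network <- function(seed = 1) {
  fixture(paste0("tiny_net_", seed), {
    preload_attractors(build_network(tiny_layout(), connectivity_params(),
                                     seed = seed))
  })
}

# the reduced-scale semantization experiment: item-cued task, both rules,
# several independently seeded trials (shared across acceptance tests).
# Each trial additionally carries post-encoding associative EPSPs of the
# trained pairings (sampled connections, first-spike convention).
semantization_runs <- function(rule = "bcpnn", n_seeds = 10) {
  fixture(paste0("sem_runs_", rule, "_", n_seeds), {
    lay <- reduced_layout()
    lapply(seq_len(n_seeds), function(s) {
      net <- preload_attractors(
        build_network(lay, connectivity_params(), seed = s))
      sched <- build_schedule(experiment_config(
        if (rule == "stdp") "stdp" else "item-cued"), net, seed = s)
      tr <- run_trial(net, sched, rule = rule, seed = s, raster = FALSE)
      map <- tr$association_map
      ps <- tr$plastic_synapses
      pairing <- which(paste(ps$item_pattern, ps$context_pattern) %in%
                         paste(map$item, map$context) &
                         ps$direction == "item_to_context")
      set.seed(s)
      take <- sample(pairing, min(40, length(pairing)))
      pl <- which(net$synapses$plastic)
      snap <- tr$snapshots$post_encoding
      tr$assoc_psp <- cbind(
        measure_psp(net, synapses = pl[take],
                    weights = list(wA = snap$wA[take], wN = snap$wN[take])),
        assoc = as.integer(table(map$item)[as.character(
          ps$item_pattern[take])]))
      tr
    })
  })
}

recall_by_assoc <- function(trials) {
  oc <- do.call(rbind, lapply(trials, `[[`, "outcomes"))
  oc$success <- oc$outcome == "remember"
  aggregate(success ~ assoc, oc, mean)
}

pairing_weights_by_assoc <- function(trials, direction = "item_to_context") {
  sm <- summarize_distributions(trials)
  w <- sm$weights[sm$weights$direction == direction, , drop = FALSE]
  aggregate(cbind(wA, wN) ~ assoc, w, mean)
}
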