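# Two-network architecture: populations, connectivity, delays, preloading.

test_that("tiny network respects layout arithmetic and class constraints", {
  net <- tiny_network()
  lay <- tiny_layout()
  nn <- net$neurons
  expect_equal(sum(nn$type == "pyr"),
               2 * lay$n_hc * lay$n_mc_per_hc * lay$pyr_per_mc)
  expect_equal(sum(nn$type == "basket"),
               2 * lay$n_hc * lay$n_mc_per_hc * lay$basket_per_mc)
  # one stored pattern spans n_hc MCs x 30 cells per network
  expect_equal(length(pattern_cells(net, "Item", 1)),
               lay$n_hc * lay$pyr_per_mc)
  syn <- net$synapses
  # no recurrent synapse crosses networks; no associative synapse stays within
  same_net <- nn$network[syn$pre] == nn$network[syn$post]
  expect_true(all(same_net[syn$class != "assoc"]))
  expect_true(all(!same_net[syn$class == "assoc"]))
  # all delays at or above the minimal synaptic delay
  expect_true(all(syn$delay >= 1.5))
  # basket wiring stays within one hypercolumn
  bk <- syn$class %in% c("pyr_ba", "ba_pyr")
  expect_true(all(nn$hc[syn$pre[bk]] == nn$hc[syn$post[bk]]))
})

test_that("connectivity is Bernoulli-consistent with the stated probabilities", {
  net <- tiny_network()
  lay <- tiny_layout()
  conn <- net$conn
  nn <- net$neurons
  syn <- net$synapses
  # same-pattern fan-in per pyramidal cell: cp_pp within-HC pairs of the
  # same MC plus cp_ppl cross-HC same-pattern pairs
  n_within <- lay$pyr_per_mc - 1
  n_cross <- (lay$n_hc - 1) * lay$pyr_per_mc
  expected <- conn$cp_pp * n_within + conn$cp_ppl * n_cross
  exc <- syn$class == "rec_exc"
  fan_in <- tabulate(syn$post[exc], nbins = nrow(nn))
  pyr_ids <- nn$id[nn$type == "pyr"]
  m <- mean(fan_in[pyr_ids])
  sd3 <- 3 * sqrt(expected) / sqrt(length(pyr_ids))
  expect_lt(abs(m - expected), sd3 + 0.5)
  # associative in-degree ~ Binomial(n_pyr_other, cp_ppa), variance at 3 sigma
  n_other <- sum(nn$network == "Item" & nn$type == "pyr")
  a_in <- tabulate(syn$post[syn$class == "assoc"], nbins = nrow(nn))[pyr_ids]
  expect_lt(abs(mean(a_in) - n_other * conn$cp_ppa),
            3 * sqrt(n_other * conn$cp_ppa) / sqrt(length(pyr_ids)) + 0.2)
  v <- var(a_in)
  vb <- n_other * conn$cp_ppa * (1 - conn$cp_ppa)
  expect_lt(abs(v - vb) / vb, 0.2)
})

test_that("the same seed reproduces the network, different seeds do not", {
  lay <- tiny_layout()
  a <- build_network(lay, seed = 7)
  b <- build_network(lay, seed = 7)
  c <- build_network(lay, seed = 8)
  expect_identical(a$synapses, b$synapses)
  expect_false(nrow(a$synapses) == nrow(c$synapses) &&
                 all(a$synapses$pre == c$synapses$pre))
})

test_that("delay sampling follows distance, speed, jitter and truncation", {
  set.seed(1)
  expect_equal(mean(sample_delay(rep(0, 2000), 0.2, jitter = 0)), 1.5)
  d <- sample_delay(rep(10, 1e5), 2)          # internetwork at myelinated speed
  expect_equal(mean(d), 6.5, tolerance = 0.01)
  expect_equal(sd(d) / mean(d), 0.3, tolerance = 0.02)
  expect_true(all(sample_delay(rep(0.1, 1e4), 0.2) >= 1.5))
  expect_error(sample_delay(1, 0), "speed")
  expect_error(sample_delay(-1, 1), "distance")
})

test_that("preloading realises the stated weight structure", {
  net <- tiny_network()
  syn <- net$synapses
  nn <- net$neurons
  within <- nn$hc[syn$pre] == nn$hc[syn$post]
  exc_w <- syn$class == "rec_exc" & within
  inh <- syn$class == "rec_inh"
  expect_equal(mean(syn$units[exc_w]), 2.15, tolerance = 0.05)
  expect_equal(mean(syn$units[inh]), -0.3, tolerance = 0.02)
  # attractor conductances positive, competing-MC weights routed as GABA
  expect_true(all(syn$wA[exc_w] > 0))
  expect_true(all(syn$wG[inh] >= 0))
  expect_true(all(syn$wA[inh] == 0))
  # a pattern's own cells receive no negative recurrent weights from itself
  same_pat <- nn$pattern[syn$pre] == nn$pattern[syn$post]
  expect_true(all(!same_pat[inh]))
  expect_error(preload_attractors(build_network(tiny_layout(), seed = 1,
    association_map = data.frame(item = integer(), context = integer()))),
    "pattern book")
})

test_that("within-HC attractor EPSPs match the calibration target", {
  net <- tiny_network()
  d <- psp_distribution(net, "rec_exc_within", n_sample = 150, seed = 2)
  expect_equal(mean(d$psp), 0.45, tolerance = 0.05)
  expect_gt(sd(d$psp), 0.05)
  # the measurement harness reports both STP conventions
  bare <- psp_distribution(net, "rec_exc_within", n_sample = 20, seed = 2,
                           stp = "bare")
  scaled <- psp_distribution(net, "rec_exc_within", n_sample = 20, seed = 2)
  expect_gt(mean(bare$psp), 2 * mean(scaled$psp))
})

test_that("network serialization round-trips through the TSV table", {
  net <- tiny_network()
  f <- tempfile(fileext = ".tsv")
  write_network(net, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(net$synapses))
  expect_equal(tab$pre, net$synapses$pre)
  expect_equal(tab$wG, net$synapses$wG, tolerance = 1e-9)
  unlink(f)
})

test_that("a cued pattern completes and sustains attractor activity", {
  # after preloading, a 50 ms cue produces a detected attractor activation
  # lasting at least 40 ms (6-HC model; a 2-HC patch lacks the recurrent
  # fan-in to sustain attractors)
  trials <- semantization_runs("bcpnn", 10)
  tr <- trials[[1]]
  t_test <- tr$schedule$t_test
  ev <- tr$events
  ev_item <- ev[ev$network == "Item" & ev$onset >= t_test, , drop = FALSE]
  expect_gte(nrow(ev_item), 1)
  expect_gte(max(ev_item$duration), 40)
})
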