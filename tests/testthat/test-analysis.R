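# Attractor-activation detector, recall scoring and the PSP harness.

test_that("EMA rate is calibrated to the true population rate", {
  emp <- ema_params()
  # exact geometric steady state: constant per-neuron rate f gives f
  set.seed(5)
  cells <- 1:30
  t_end <- 2000
  f <- 20
  st <- sort(runif(30 * f * t_end / 1000) * t_end)
  ids <- sample(cells, length(st), replace = TRUE)
  r <- ema_rate(st, ids, cells, t_end, emp)
  late <- r$rate[r$time > 5 * emp$tau]
  expect_equal(mean(late), f, tolerance = 0.05 * f)
  # steady-state calibration across rates (property)
  for (f in c(1, 10, 50)) {
    n_sp <- round(30 * f * 2)
    st <- seq(0, 2000, length.out = n_sp)
    ids <- rep(cells, length.out = n_sp)
    r <- ema_rate(st, ids, cells, 2000, emp)
    expect_lt(abs(mean(r$rate[r$time > 1000]) - f) / f, 0.02)
  }
})

test_that("EMA impulse response decays with the filter time constant", {
  emp <- ema_params()
  r <- ema_rate(rep(100, 30), 1:30, 1:30, 600, emp)
  pk <- max(r$rate)
  at <- r$rate[r$time == 100 + 40]
  expect_equal(at / pk, exp(-1), tolerance = 0.05)
  expect_true(all(ema_rate(numeric(), integer(), 1:30, 500, emp)$rate == 0))
  expect_error(ema_rate(numeric(), integer(), integer(), 500, emp),
               "non-empty")
})

test_that("event detection applies threshold, minimal duration and re-cross guard", {
  emp <- ema_params()
  mk <- function(segments) unlist(lapply(segments, function(s)
    rep(s[1], s[2])))
  # always sub-threshold
  expect_equal(nrow(detect_events(rep(5, 500), emp)), 0)
  # 100 ms plateau with a 20 ms dip: one event, not two
  r <- mk(list(c(0, 100), c(30, 40), c(5, 20), c(30, 40), c(0, 100)))
  ev <- detect_events(r, emp)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$duration, 100)
  # 30 ms supra-threshold blip is discarded
  r <- mk(list(c(0, 100), c(30, 30), c(0, 100)))
  expect_equal(nrow(detect_events(r, emp)), 0)
  # a long dip splits two events
  r <- mk(list(c(0, 50), c(30, 60), c(5, 80), c(30, 60), c(0, 50)))
  expect_equal(nrow(detect_events(r, emp)), 2)
})

test_that("detection is idempotent and robust to sub-threshold noise", {
  emp <- ema_params()
  set.seed(8)
  base <- c(rep(0, 200), rep(25, 120), rep(0, 300), rep(18, 90), rep(0, 100))
  ev1 <- detect_events(base, emp)
  expect_equal(nrow(ev1), 2)
  for (rep in 1:10) {
    noisy <- pmax(0, base + runif(length(base), -4.9, 4.9))
    ev2 <- detect_events(noisy, emp)
    expect_equal(nrow(ev2), nrow(ev1))
  }
  # independence of chunking: same result when computed from a data frame
  df <- data.frame(time = seq_along(base), rate = base)
  expect_equal(detect_events(df, emp), detect_events(base, emp))
})

test_that("recall outcomes implement the Remember/Know distinction", {
  map <- data.frame(item = c(1, 1, 2), context = c(3, 4, 5))
  ev <- data.frame(network = c("Item", "Context"), pattern = c(1, 3),
                   onset = c(100, 150))
  cue <- list(network = "Item", pattern = 1, window = c(90, 500))
  expect_equal(score_recall(ev, cue, map)$outcome, "remember")
  # item only
  ev2 <- ev[1, ]
  expect_equal(score_recall(ev2, cue, map)$outcome, "know")
  # no event at all
  ev3 <- ev[integer(0), ]
  expect_equal(score_recall(ev3, cue, map)$outcome, "miss")
  # a non-associated context does not count as recollection
  ev4 <- data.frame(network = c("Item", "Context"), pattern = c(1, 5),
                    onset = c(100, 150))
  expect_equal(score_recall(ev4, cue, map)$outcome, "know")
  # symmetric logic for context cues
  cue2 <- list(network = "Context", pattern = 3, window = c(90, 500))
  ev5 <- data.frame(network = c("Context", "Item"), pattern = c(3, 1),
                    onset = c(100, 160))
  expect_equal(score_recall(ev5, cue2, map)$outcome, "remember")
  expect_error(score_recall(ev, list(network = "Item", pattern = 9,
                                     window = c(0, 1)), map), "unknown")
})

test_that("PSP measurement matches the linearised analytic oracle", {
  net <- tiny_network()
  par <- net$params$neuron
  for (g in c(0.3, 0.6)) {
    sim <- .engine_psp_peak(unclass(par), par[["E_L"]], cbind(g, 5, 0),
                            0.01, 300)
    ana <- ref_psp_peak_linear(g, 5, 0, par[["E_L"]], par)
    expect_equal(sim, ana, tolerance = 0.02)
  }
  # holding at the reversal potential: zero deflection
  z <- .engine_psp_peak(unclass(par), 0, cbind(0.5, 5, 0), 0.01, 100)
  expect_lt(abs(z), 1e-9)
})

test_that("measure_psp reports connections and flags unconnected pairs", {
  net <- tiny_network()
  syn1 <- which(net$synapses$class == "rec_exc")[1]
  r <- measure_psp(net, synapses = syn1)
  expect_true(r$connected)
  expect_gt(r$psp, 0)
  # a zero-weight connection deflects nothing
  net2 <- net
  net2$synapses$wA[syn1] <- 0
  net2$synapses$wN[syn1] <- 0
  expect_equal(measure_psp(net2, synapses = syn1)$psp, 0)
  # unconnected pair: explicit no-connection result
  nn <- net$neurons
  pre <- nn$id[nn$type == "basket"][1]
  post <- nn$id[nn$type == "basket"][2]
  r2 <- measure_psp(net, pre = pre, post = post)
  expect_false(r2$connected)
  expect_true(is.na(r2$psp))
})

test_that("summarize_distributions returns empty tables for no trials", {
  s <- summarize_distributions(list())
  expect_equal(nrow(s$weights), 0)
  expect_equal(nrow(s$bias), 0)
})
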