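# Spike-based Bayesian-Hebbian trace cascade, weights, bias and kappa gating.

test_that("Z trace decays to the probability floor and saturates near 1 at f_max", {
  par <- bcpnn_params()
  # no spikes: decay to eps
  z <- z_update(0.5, rep(0, 5000), tau_z = 5, par, dt = 0.1)
  expect_equal(tail(z, 1), par$eps, tolerance = 1e-4)
  # sustained firing at f_max = 25 Hz: time-averaged Z ~ 1 (NMDA bank)
  set.seed(3)
  dt <- 0.1
  n <- 10000 / dt                              # 10 s
  spikes <- runif(n) < 25 * 1e-3 * dt
  z <- z_update(par$eps, spikes, tau_z = 100, par, dt = dt)
  zbar <- mean(z[(n / 2):n])
  expect_gt(zbar, 0.85)
  expect_lt(zbar, 1.15)
})

test_that("Z update matches the fine-step oracle on a fixed train", {
  pre <- c(10, 60, 61.5, 200, 420, 421, 480)
  oracle <- ref_bcpnn_traces(pre, numeric(), t_max = 600, tau_z = 100,
                             dt = 0.01)
  spikes <- rep(0, 6000)
  spikes[round(pre / 0.1) + 1] <- 1
  z <- z_update(bcpnn_params()$eps, spikes, tau_z = 100, dt = 0.1)
  expect_equal(tail(z, 1), oracle$Z_i, tolerance = 0.02)
})

test_that("P traces follow their linear filter and freeze at kappa zero", {
  par <- bcpnn_params()
  p0 <- list(P_i = 0.2, P_j = 0.3, P_ij = 0.05)
  z <- rep(0.8, 1000)
  # kappa = 0: bit-identical
  frozen <- p_update(p0, z, z, par, kappa = 0, dt = 1)
  expect_true(all(frozen$P_i == 0.2) && all(frozen$P_ij == 0.05))
  # constant Z = c: exponential approach with time constant tau_p / kappa
  n <- 30000                                  # 30 s at dt = 1 ms
  p <- p_update(list(P_i = 0, P_j = 0, P_ij = 0), rep(0.6, n), rep(0.6, n),
                par, kappa = 1, dt = 1)
  t15 <- p$P_i[15000]                          # one tau_p
  expect_equal(t15, 0.6 * (1 - exp(-1)), tolerance = 0.01)
  p2 <- p_update(list(P_i = 0, P_j = 0, P_ij = 0), rep(0.6, n), rep(0.6, n),
                 par, kappa = 2, dt = 1)
  expect_equal(p2$P_i[7500], t15, tolerance = 0.01)  # twice as fast
})

test_that("independent pre/post activity factorises the coactivation trace", {
  par <- bcpnn_params()
  set.seed(11)
  dt <- 1
  n <- 400000                                  # 400 s
  ratios <- replicate(8, {
    si <- as.numeric(runif(n) < 10 * 1e-3 * dt)
    sj <- as.numeric(runif(n) < 10 * 1e-3 * dt)
    zi <- z_update(par$eps, si, tau_z = 100, par, dt = dt)
    zj <- z_update(par$eps, sj, tau_z = 100, par, dt = dt)
    p <- p_update(bcpnn_traces(par)[c("P_i", "P_j", "P_ij")], zi, zj, par,
                  dt = dt)
    m <- n / 2
    mean(p$P_ij[m:n]) / (mean(p$P_i[m:n]) * mean(p$P_j[m:n]))
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("weights and bias are the log-odds of the P traces", {
  par <- bcpnn_params()
  wb <- weight_and_bias(list(P_i = 0.2, P_j = 0.4, P_ij = 0.08), par)
  expect_equal(wb$w, 0)                        # P_ij = P_i P_j
  wb <- weight_and_bias(list(P_i = 0.5, P_j = 0.5, P_ij = 0.5), par,
                        receptor = "AMPA")
  expect_equal(wb$w, 0.76 * log(2), tolerance = 1e-10)
  expect_equal(weight_and_bias(list(P_i = 1, P_j = 1, P_ij = 1),
                               par)$beta, 0)
  expect_error(weight_and_bias(list(P_i = 0, P_j = 0.5, P_ij = 0.1), par),
               "positive")
})

test_that("signed weights route to the appropriate reversal", {
  expect_equal(apply_plastic_weight(0)$g, 0)
  r <- apply_plastic_weight(1, "AMPA")
  expect_equal(r$receptor, "AMPA")
  r <- apply_plastic_weight(-1, "AMPA")
  expect_equal(r$receptor, "GABA")
  expect_equal(r$g, 1)
  # sign of the membrane deflection: EPSP at rest, IPSP at -60 mV
  p <- default_config()
  up <- .engine_psp_peak(unclass(p$neuron), -70.6, cbind(1, 5, 0), 0.01, 200)
  dn <- .engine_psp_peak(unclass(p$neuron), -60, cbind(1, 5, -75), 0.01, 200)
  expect_gt(up, 0)
  expect_lt(dn, 0)
})

test_that("mirrored spike trains give symmetric weights", {
  par <- bcpnn_params()
  pre <- c(50, 120, 300, 310, 700, 950)
  a <- ref_bcpnn_traces(pre, pre + 3, 1200, tau_z = 100)
  b <- ref_bcpnn_traces(pre + 3, pre, 1200, tau_z = 100)
  wa <- weight_and_bias(a, par)$w
  wb <- weight_and_bias(b, par)$w
  expect_equal(wa, wb, tolerance = 0.02)
})

test_that("set_kappa validates input and registers an override", {
  net <- tiny_network()
  expect_error(set_kappa(net, -1), "non-negative")
  net2 <- set_kappa(net, 0)
  expect_length(net2$kappa_overrides, 1)
  expect_equal(net2$kappa_overrides[[1]]$kappa, 0)
})

test_that("a frozen network's plastic state is bit-identical over a simulated interval", {
  net <- tiny_network()
  net0 <- set_kappa(net, 0)
  sched <- build_schedule(experiment_config("item-cued", n_trials = 1),
                          net0, seed = 4)
  tr <- run_trial(net0, sched, "bcpnn", seed = 4, raster = FALSE)
  tt <- bcpnn_trace_table(tr)
  e <- net$params$bcpnn$eps
  expect_true(all(tt$P_i_NMDA == e))
  expect_true(all(tt$P_ij_NMDA == e^2))
  expect_true(all(tt$P_ij_AMPA == e^2))
  # weights identically zero before and after
  expect_true(all(tr$snapshots$end$wA == 0))
  expect_true(all(tr$snapshots$end$wN == 0))
})

test_that("engine traces match the fine-step reference on identical spike trains", {
  # drive two microcircuit neurons deterministically and compare the
  # engine's per-synapse traces with the independent reference integration
  mb <- run_microcircuit(rule = "bcpnn")
  sp <- mb$raster
  pre <- sp$time[sp$neuron == 1]
  post <- sp$time[sp$neuron == 3]
  oracle <- ref_bcpnn_traces(pre, post, 12000, tau_z = 100, dt = 0.05)
  fin <- trace_inspect(mb, "1->3", 11.999)
  expect_equal(fin$P_i, oracle$P_i, tolerance = 0.02)
  expect_equal(fin$P_j, oracle$P_j, tolerance = 0.02)
  expect_equal(fin$P_ij, oracle$P_ij, tolerance = 0.03)
})
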