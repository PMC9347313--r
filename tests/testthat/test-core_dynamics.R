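# AdEx neuron, conductance synapses, short-term plasticity, background noise.

test_that("perturbed membrane relaxes to rest with the passive time constant", {
  par <- neuron_params()
  ref <- ref_adex_subthreshold(par[["E_L"]] + 1, par, t_max = 100)
  st <- neuron_state(par, V_m = par[["E_L"]] + 1)
  dt <- 0.1
  volts <- numeric(1000)
  for (k in 1:1000) {
    st <- adex_step(st, par, dt = dt)$state
    volts[k] <- st$V_m
  }
  # agree with the dt = 0.001 reference
  idx <- seq(100, 1000, by = 100)
  ref_v <- ref$V[round(idx * dt / 0.001) + 1]
  expect_equal(volts[idx], ref_v, tolerance = 1e-3)
  # effective time constant ~ C_m / g_L = 20 ms (slightly longer with the
  # exponential term): the deviation falls to 1/e between 19 and 22 ms
  dev <- abs(volts - par[["E_L"]])
  t_e <- which(dev < exp(-1))[1] * dt
  expect_gt(t_e, 19)
  expect_lt(t_e, 22)
})

test_that("spike resets the membrane, increments adaptation and enforces refractoriness", {
  par <- neuron_params()
  st <- neuron_state(par, V_m = -50)
  out <- list(state = st, spiked = FALSE)
  for (k in 1:2000) {                      # strong drive until spike
    out <- adex_step(out$state, par, I_ext = 600, dt = 0.1)
    if (out$spiked) break
  }
  expect_true(out$spiked)
  expect_equal(out$state$V_m, -60)          # V_r from the parameter table
  expect_equal(out$state$I_w, 86, tolerance = 1e-6)  # b increment
  expect_equal(out$state$refractory, 5)
  # membrane clamped at V_r during refractoriness despite the drive
  st2 <- adex_step(out$state, par, I_ext = 600, dt = 0.1)$state
  expect_equal(st2$V_m, -60)
  expect_equal(st2$refractory, 4.9)
})

test_that("adaptation current decays with its closed-form time course", {
  par <- neuron_params()
  st <- neuron_state(par, I_w = 86)
  for (k in 1:1000) st <- adex_step(st, par, dt = 0.1)$state  # 100 ms
  expect_equal(st$I_w, 86 * exp(-100 / 280), tolerance = 1e-3)
})

test_that("adex_step rejects invalid input", {
  par <- neuron_params()
  st <- neuron_state(par)
  expect_error(adex_step(st, par, dt = 0), "dt")
  expect_error(adex_step(st, par, dt = -1), "dt")
  st$V_m <- NaN
  expect_error(adex_step(st, par, dt = 0.1), "finite")
})

test_that("subthreshold fixed point equals the leak reversal to within 0.1 mV", {
  expect_lt(abs(adex_fixed_point(neuron_params()) - (-70.6)), 0.1)
})

test_that("synaptic currents follow the conductance-based sign convention", {
  # zero driving force at each reversal
  expect_equal(synaptic_current(0, c(AMPA = 2)), 0)
  expect_equal(synaptic_current(-75, c(GABA = 3)), 0)
  # GABA at -60 mV: 7 nS * 15 mV = 105 pA, hyperpolarising (positive here)
  expect_equal(synaptic_current(-60, c(GABA = 7)), 105)
  # AMPA below reversal is depolarising (negative)
  expect_lt(synaptic_current(-70, c(AMPA = 1)), 0)
  expect_equal(synaptic_current(-60, numeric()), 0)
  expect_error(synaptic_current(-60, c(ACH = 1)), "receptor")
  expect_error(synaptic_current(-60, c(AMPA = -1)), "non-negative")
})

test_that("short-term plasticity jumps and fixed point match the update rule", {
  # single spike from rest: u+ = U = 0.2, x after depletion = 0.8
  s <- stp_update(list(u = 0, x = 1), stp_params(), spike = TRUE, dt = 1e-9)
  expect_equal(s$u, 0.2, tolerance = 1e-6)
  expect_equal(s$x, 0.8, tolerance = 1e-6)
  expect_equal(s$release, 0.2, tolerance = 1e-6)  # u+ * x-
  # long silence: (u, x) -> (0, 1)
  s <- list(u = 0.7, x = 0.3)
  for (k in 1:600) s <- stp_update(s, stp_params(), FALSE, dt = 100)[c("u", "x")]
  expect_equal(s$u, 0, tolerance = 1e-4)
  expect_equal(s$x, 1, tolerance = 1e-4)
})

test_that("periodic-train STP state matches the event-by-event oracle", {
  spikes_at <- seq(0, 2000, by = 50)       # 20 Hz for 2 s
  oracle <- ref_stp_train(spikes_at)
  s <- list(u = 0, x = 1)
  dt <- 0.1
  for (k in seq_len(2000 / dt + 1)) {
    t <- (k - 1) * dt
    s <- stp_update(s, stp_params(), spike = any(abs(spikes_at - t) < dt / 2),
                    dt = dt)[c("u", "x")]
  }
  expect_equal(s$u, oracle$u, tolerance = 1e-3)
  expect_equal(s$x, oracle$x, tolerance = 1e-3)
})

test_that("u and x stay within [0, 1] under random spike trains", {
  set.seed(42)
  ok <- TRUE
  for (rep in 1:20) {
    s <- list(u = runif(1), x = runif(1))
    for (k in 1:500) {
      s <- stp_update(s, stp_params(), spike = runif(1) < 0.3, dt = 5)[c("u", "x")]
      ok <- ok && s$u >= 0 && s$u <= 1 && s$x >= 0 && s$x <= 1
    }
  }
  expect_true(ok)
})

test_that("poisson background has the stated rate and structure", {
  expect_equal(nrow(poisson_background(0, duration = 1000)), 0)
  ev <- poisson_background(650, duration = 10000, seed = 7)
  n_exc <- sum(ev$stream == "exc")
  n_inh <- sum(ev$stream == "inh")
  expect_lt(abs(n_exc - 6500), 3 * sqrt(6500))
  expect_lt(abs(n_inh - 6500), 3 * sqrt(6500))
  # opposing driving potentials: the symmetric point of the reversals has
  # zero mean current
  Vmid <- mean(c(0, -75))
  I <- sum(ev$g * (Vmid - ev$E_rev))
  expect_lt(abs(I) / nrow(ev), 1.5 * 37.5 * 0.05)  # within 5% of magnitude
  expect_error(poisson_background(-10), "non-negative")
})

test_that("halving dt changes single-neuron spike times by less than 0.5 ms", {
  par <- neuron_params()
  # frozen input producing a plausible cortical rate (~7 Hz) over 1 s
  drive <- function(t) 300 + 100 * sin(2 * pi * t / 180)
  run <- function(dt) {
    st <- neuron_state(par)
    spikes <- numeric()
    for (k in seq_len(round(1000 / dt))) {
      t <- k * dt
      out <- adex_step(st, par, I_ext = drive(t), dt = dt)
      st <- out$state
      if (out$spiked) spikes <- c(spikes, t)
    }
    spikes
  }
  s1 <- run(0.1)
  s2 <- run(0.05)
  expect_gt(length(s1), 5)
  n <- min(length(s1), length(s2))
  expect_lt(max(abs(s1[1:n] - s2[1:n])), 0.5)
})

test_that("no two spikes of one neuron occur within the refractory period", {
  par <- neuron_params()
  st <- neuron_state(par)
  spikes <- numeric()
  for (k in 1:20000) {                     # 2 s of very strong drive
    out <- adex_step(st, par, I_ext = 2000, dt = 0.1)
    st <- out$state
    if (out$spiked) spikes <- c(spikes, k * 0.1)
  }
  expect_gt(length(spikes), 10)
  expect_true(all(diff(spikes) >= 5))
})
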