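# Stimulus schedules, trial determinism and experiment plumbing.

test_that("the default item-cued schedule has the stated structure", {
  net <- tiny_network()
  sched <- build_schedule(experiment_config("item-cued"), net, seed = 1)
  e <- sched$encoding
  expect_equal(nrow(e), 10)                   # one epoch per pairing
  expect_true(all(e$duration == 250))
  expect_equal(unique(diff(sort(e$onset))), 750)  # 500 ms interstimulus gap
  expect_true(all(e$rate == 500) && all(e$g == 1.5))
  # a settling period precedes the first epoch
  expect_gte(min(e$onset), 500)
  # test begins 1 s after encoding ends; cues are 50 ms at 400 Hz
  expect_equal(sched$t_test - sched$t_enc_end, 1000)
  expect_equal(nrow(sched$cues), 4)
  expect_true(all(sched$cues$duration == 50))
  expect_true(all(sched$cues$rate == 400))
  expect_setequal(sched$cues$pattern, 1:4)
  expect_true(all(sched$cues$network == "Item"))
  # epochs do not overlap within a target population
  expect_true(all(diff(sort(e$onset)) >= e$duration[1]))
})

test_that("variant schedules cue the stated populations", {
  net <- tiny_network()
  ctx <- build_schedule(experiment_config("context-cued"), net, seed = 1)
  expect_equal(nrow(ctx$cues), 10)
  expect_true(all(ctx$cues$network == "Context"))
  mc <- build_schedule(experiment_config("multi-cue"), net, seed = 1)
  # the four contexts of the 4-association item form one contiguous group
  g4 <- mc$cues[mc$cues$assoc == 4, ]
  expect_equal(length(unique(g4$group)), 1)
  expect_equal(nrow(g4), 4)
  expect_equal(max(diff(sort(g4$onset))), 500)
  # empty association map: settling and delay only
  empty <- build_schedule(
    experiment_config("item-cued",
                      association_map = data.frame(item = integer(),
                                                   context = integer())),
    net, seed = 1)
  expect_equal(nrow(empty$encoding), 0)
  expect_equal(nrow(empty$cues), 0)
  expect_error(build_schedule(
    experiment_config("item-cued",
                      association_map = data.frame(item = 1, context = 99)),
    net, seed = 1), "unknown patterns")
  expect_error(build_schedule(
    experiment_config("item-cued",
                      association_map = data.frame(item = c(1, 2),
                                                   context = c(1, 1))),
    net, seed = 1), "at most once")
})

test_that("the kappa-boost epoch covers exactly the boosted pairing's encoding", {
  net <- tiny_network()
  cfg <- experiment_config("preferential-retention",
                           boost_pair = c(item = 1, context = 5))
  sched <- build_schedule(cfg, net, seed = 3)
  expect_length(sched$kappa_epochs, 1)
  ke <- sched$kappa_epochs[[1]]
  expect_equal(ke$kappa, 2)                    # kappa_boost
  row <- which(sched$association_map$item == 1 &
                 sched$association_map$context == 5)
  expect_equal(ke$start, sched$encoding$onset[row])
  expect_equal(ke$end, sched$encoding$onset[row] + 250)
  expect_error(build_schedule(
    experiment_config("preferential-retention",
                      boost_pair = c(item = 3, context = 5)), net, 3),
    "not a pairing")
})

test_that("identically seeded trials are bit-reproducible", {
  net <- tiny_network()
  sched <- build_schedule(experiment_config("item-cued"), net, seed = 5)
  a <- run_trial(net, sched, "bcpnn", seed = 5)
  b <- run_trial(net, sched, "bcpnn", seed = 5)
  expect_identical(a$raster, b$raster)
  expect_identical(a$snapshots, b$snapshots)
  c <- run_trial(net, sched, "bcpnn", seed = 6)
  expect_false(identical(a$raster, c$raster))
})

test_that("toggling augmentation pins utilization to U", {
  net <- toggle_augmentation(tiny_network(), FALSE)
  expect_false(net$params$stp$augmentation)
  s <- list(u = 0, x = 1)
  p <- stp_params(augmentation = FALSE)
  for (k in 1:5) s <- stp_update(s, p, spike = TRUE, dt = 10)[c("u", "x")]
  expect_equal(s$u, p$U, tolerance = 1e-9)
  # with augmentation, repeated spikes raise u above U
  s2 <- list(u = 0, x = 1)
  for (k in 1:5) s2 <- stp_update(s2, stp_params(), TRUE, dt = 10)[c("u", "x")]
  expect_gt(s2$u, p$U)
  # the no-augmentation variant applies the compensation multipliers
  sched <- build_schedule(experiment_config("stdp-no-augmentation"), net, 1)
  expect_false(sched$augmentation)
  expect_gt(sched$encoding$rate[1], 500)
  expect_gt(sched$encoding$g[1], 1.5)
})

test_that("single-trial experiments report Bernoulli dispersion of zero", {
  res <- run_experiment(experiment_config("item-cued", n_trials = 1),
                        layout = tiny_layout(), seed = 3)
  expect_true(all(res$recall$sd == 0))
  expect_true(all(res$recall$recall %in% c(0, 1)))
  expect_true(all(res$recall$n_trials == 1))
})

test_that("config files round-trip through YAML with table keys", {
  cfg <- default_config(stp = stp_params(U = 0.25))
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  txt <- readLines(f)
  expect_true(any(grepl("C_m", txt)))          # table symbol preserved
  cfg2 <- read_config(f)
  expect_equal(cfg2$stp$U, 0.25)
  expect_equal(unclass(cfg2$neuron), unclass(cfg$neuron))
  expect_equal(cfg2$connectivity$cp_ppa, 0.02)
  unlink(f)
})
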