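test_that("degenerate generator limits: regular and Poisson trains", {
  # no bursts, near-infinite shape -> regular train
  s <- simulate_spike_train(10, cv = 0, burst_index = 0, duration = 120,
                            seed = 1, refractory = 0)
  st <- spike_stats(s, 120)
  expect_lt(abs(st$rate - 10), 0.5)
  expect_lt(st$cv, 0.05)
  expect_equal(st$burst_index, 0)

  # shape 1 (cv target 1), no bursts -> Poisson-like ISIs
  s <- simulate_spike_train(5, cv = 1, burst_index = 0, duration = 2000,
                            seed = 2, refractory = 0)
  st <- spike_stats(s, 2000)
  expect_gt(st$cv, 0.95)
  expect_lt(st$cv, 1.05)
})

test_that("same spec and seed give identical spike times", {
  a <- simulate_spike_train(7, 1.2, 0.2, 60, seed = 99)
  b <- simulate_spike_train(7, 1.2, 0.2, 60, seed = 99)
  expect_identical(a, b)
  pop1 <- simulate_population(n_per_type = 3, duration = 30, seed = 4)
  pop2 <- simulate_population(n_per_type = 3, duration = 30, seed = 4)
  expect_identical(pop1$neurons$spikes, pop2$neurons$spikes)
  expect_identical(pop1$labels, pop2$labels)
})

test_that("populations have the requested size and shuffled labels", {
  pop <- simulate_population(n_per_type = 70, duration = 5, seed = 3)
  expect_equal(nrow(pop$neurons), 280)
  expect_equal(sort(unique(pop$labels$type)), 1:4)
  expect_equal(as.integer(table(pop$labels$type)), rep(70L, 4))
  expect_setequal(pop$neurons$neuron_id, pop$labels$neuron_id)
  expect_error(simulate_population(n_per_type = 0, seed = 1), "n_per_type")
  expect_error(simulate_population(lhb_type_presets()[1, ], 2, 10, 1),
               "two type presets")
})

test_that("preset targets are recovered: anesthetized rate ordering and awake Type-1", {
  pr_an <- lhb_type_presets("anesthetized")
  pop <- simulate_population(pr_an, n_per_type = 15, duration = 120, seed = 21)
  fe <- compute_features(pop$neurons)
  fe$type <- pop$labels$type[match(fe$neuron_id, pop$labels$neuron_id)]
  mean_rate <- tapply(fe$rate, fe$type, mean)
  # published ordering: 2.07 < 3.45 < 10.67 < 19.57
  expect_true(all(diff(mean_rate) > 0))

  # awake Type-1 targets (7.15, 1.57, 0.24) within +-30% over repeated draws
  pr_aw <- lhb_type_presets("awake")
  st <- dplyr::bind_rows(lapply(1:20, function(i) {
    v <- withr::with_seed(3000 + i,
      habclust:::draw_type_params(1, pr_aw, dispersion_scale = 0.3))
    s <- simulate_spike_train(v[1], v[2], v[3], 120, seed = 4000 + i,
                              burst_len = 3, intra = c(0.003, 0.010))
    spike_stats(s, 120)
  }))
  expect_lt(abs(mean(st$rate) / 7.15 - 1), 0.3)
  expect_lt(abs(mean(st$cv) / 1.57 - 1), 0.3)
  expect_lt(abs(mean(st$burst_index) / 0.24 - 1), 0.3)
})

test_that("identical specs for two nominal types defeat clustering (negative control)", {
  pr <- lhb_type_presets()[c(3, 3), ]
  pr$type <- 1:2
  pop <- simulate_population(pr, n_per_type = 30, duration = 60, seed = 8)
  ft <- build_feature_table(compute_features(pop$neurons))
  mod <- fit_gmm(ft, 2, n_restarts = 10, seed = 9)
  lab <- pop$labels$type[match(tidy(mod)$neuron_id, pop$labels$neuron_id)]
  expect_lt(adjusted_rand_index(tidy(mod)$cluster, lab), 0.15)
})

test_that("shock sessions express the planted response kind", {
  # no modulation -> FSMI near 0 with many trials
  fs0 <- simulate_shock_session(8, "none", n_trials = 500, seed = 11)
  expect_lt(abs(shock_modulation(fs0$neurons, fs0$trials)$fsmi), 0.05)
  # complete suppression -> FSMI = -1 exactly
  fsi <- simulate_shock_session(8, "inhibited", inhib_factor = 0,
                                n_trials = 60, seed = 12)
  expect_equal(shock_modulation(fsi$neurons, fsi$trials)$fsmi, -1)
  # trial protocol recorded
  expect_equal(fs0$trials$n_trials, 500)
  expect_true(all(diff(fs0$trials$onsets[[1]]) == 5))
})

test_that("state sessions couple rate to the motion percentile rule", {
  st <- simulate_state_session(10, active_gain = 3, session_length = 400, seed = 13)
  bm <- state_modulation(st$neurons, st$motion)
  # gain 3 -> BSMI -> 0.5
  expect_lt(abs(bm$bsmi - 0.5), 0.08)
  expect_equal(bm$category, "increase")
  # null gain -> index near zero
  st0 <- simulate_state_session(10, active_gain = 1, session_length = 400, seed = 14)
  expect_lt(abs(state_modulation(st0$neurons, st0$motion)$bsmi), 0.1)
})
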