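test_that("percentile epoching covers the expected session fractions", {
  withr::with_seed(40, {
    m <- motion_trace("s1", abs(rnorm(6000)), sample_rate = 20)
  })
  ep <- partition_states(m, smooth = 0, min_epoch = 0)
  active_t <- sum(ep$end[ep$state == "active"] - ep$start[ep$state == "active"])
  quiet_t <- sum(ep$end[ep$state == "quiet"] - ep$start[ep$state == "quiet"])
  expect_lt(abs(active_t / 300 - 0.2), 0.01)
  expect_lt(abs(quiet_t / 300 - 0.2), 0.01)
  # disjoint and inside the session
  expect_true(all(ep$start < ep$end))
  eps <- ep[order(ep$start), ]
  expect_true(all(diff(eps$start) >= (eps$end - eps$start)[-nrow(eps)] - 1e-9))
})

test_that("degenerate motion traces are rejected", {
  flat <- motion_trace("s1", rep(1, 2000), sample_rate = 10)
  expect_error(partition_states(flat), "constant")
})

test_that("a square-wave trace yields hand-computable epochs", {
  e <- rep(c(0.1, 0.9), each = 600)  # 60 s low, 60 s high at 10 Hz
  m <- motion_trace("s1", e + seq_along(e) * 1e-9, sample_rate = 10)
  ep <- partition_states(m, smooth = 0, min_epoch = 0)
  act <- ep[ep$state == "active", ]
  qui <- ep[ep$state == "quiet", ]
  # the tiny ramp breaks plateau ties: active is one run covering the top
  # 20% of samples (inside the high half), quiet the bottom 20%
  expect_equal(sum(act$end - act$start), 24, tolerance = 0.3)
  expect_equal(sum(qui$end - qui$start), 24, tolerance = 0.3)
  expect_equal(nrow(act), 1)
  expect_true(act$start >= 60)
  expect_true(qui$end <= 60.1)
})

test_that("epoching is invariant to monotone rescaling of the trace", {
  withr::with_seed(41, m0 <- abs(rnorm(4000)))
  m1 <- motion_trace("s", m0, 20)
  m2 <- motion_trace("s", m0^3, 20)    # strictly monotone transform
  e1 <- partition_states(m1, smooth = 0)
  e2 <- partition_states(m2, smooth = 0)
  expect_equal(e1$state, e2$state)
  expect_equal(e1$start, e2$start, tolerance = 1e-12)
})

test_that("BSMI reproduces its arithmetic and limits", {
  ep <- tibble::tibble(state = c("active", "active", "quiet", "quiet"),
                       start = c(0, 20, 50, 70), end = c(10, 30, 60, 80))
  # equal rates -> 0
  s_eq <- sort(c(seq(0.5, 9.5, 1), seq(20.5, 29.5, 1),
                 seq(50.5, 59.5, 1), seq(70.5, 79.5, 1)))
  expect_equal(compute_bsmi(s_eq, ep)$bsmi, 0)
  # 30 Hz active vs 10 Hz quiet -> 0.5
  s_30_10 <- sort(c(seq(0, 10 - 1e-3, by = 1 / 30), seq(20, 30 - 1e-3, by = 1 / 30),
                    seq(50, 60 - 1e-3, by = 0.1), seq(70, 80 - 1e-3, by = 0.1)))
  r <- compute_bsmi(s_30_10, ep)
  expect_equal(r$fr_active, 30, tolerance = 1e-2)
  expect_equal(r$fr_quiet, 10, tolerance = 1e-2)
  expect_equal(r$bsmi, 0.5, tolerance = 1e-3)
  # silent quiet state -> +1
  s_act <- sort(c(seq(0.5, 9.5, 1), seq(20.5, 29.5, 1)))
  expect_equal(compute_bsmi(s_act, ep)$bsmi, 1)
  # too little state time -> flagged
  short_ep <- tibble::tibble(state = c("active", "quiet"),
                             start = c(0, 5), end = c(2, 7))
  expect_true(compute_bsmi(s_eq, short_ep)$flagged)
})

test_that("per-neuron classification has sign-consistent categories", {
  # identical epoch rates -> no_change with p = 1
  rec <- tibble::tibble(fr_active = 5, fr_quiet = 5, bsmi = 0, flagged = FALSE,
                        active_rates = list(c(4, 5, 6, 5)),
                        quiet_rates = list(c(5, 6, 4, 5)))
  out <- classify_modulation(rec)
  expect_equal(out$category, "no_change")
  expect_equal(out$p_value, 1)
  # clearly shifted rates -> increase
  rec2 <- rec
  rec2$active_rates <- list(c(14, 15, 16, 15, 14, 16))
  rec2$quiet_rates <- list(c(5, 6, 4, 5, 6, 4))
  expect_equal(classify_modulation(rec2)$category, "increase")
  # too few epochs -> insufficient flag, no_change
  rec3 <- rec
  rec3$active_rates <- list(c(1, 2))
  out3 <- classify_modulation(rec3)
  expect_equal(out3$category, "no_change")
  expect_true(out3$insufficient)
})

test_that("gain-2 neurons are detected as increases in most sessions", {
  withr::with_seed(42, hits <- sapply(1:12, function(i) {
    st <- simulate_state_session(8, active_gain = 2, session_length = 300,
                                 seed = 900 + i)
    state_modulation(st$neurons, st$motion)$category == "increase"
  }))
  expect_gte(mean(hits), 0.9)
})
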