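test_that("noise-free pursuit trace reaches gain * velocity exactly", {
  obs <- quiet_observer(quiet_params(gain_first = 1))
  cond <- trial_condition("pursuit_first_order", 3)
  st <- simulate_eye_trace(cond, obs, seed = 1, pretrial_ms = 1200)
  expect_equal(st$truth$steady_velocity, 3)
  # raw velocity during the plateau equals 3 deg/s
  v <- differentiate_central(st$trace$x_deg)
  plateau <- st$trace$t_ms >= 300 & st$trace$t_ms <= 490
  expect_equal(max(abs(v[plateau] - 3)), 0, tolerance = 1e-9)
  # before onset the eye sits on the gazed object
  pre <- st$trace$t_ms < st$truth$onset_time_ms
  expect_true(all(st$trace$x_deg[pre] == -3))
})

test_that("fixation trace is noise-bounded with no saccades", {
  obs <- quiet_observer()
  cond <- trial_condition("fixation", 4)
  st <- simulate_eye_trace(cond, obs, seed = 2, pretrial_ms = 1000)
  expect_true(all(st$trace$x_deg == -3))
  expect_length(st$truth$saccade_onsets_ms, 0)
  expect_true(is.na(st$truth$onset_time_ms))
  # with noise, excursion stays within a few SD
  p <- default_sim_params()
  obs2 <- sim_observer(1, p, seed = 3)
  st2 <- simulate_eye_trace(trial_condition("fixation", 4), obs2, seed = 4)
  ok <- is.finite(st2$trace$x_deg)
  expect_lt(max(abs(st2$trace$x_deg[ok] + 3)),
            6 * p$shared$fixation_noise_sd_deg)
})

test_that("second-order onsets are later than first-order on average", {
  p <- default_sim_params()
  obs <- sim_observer(1, p, seed = 10)
  onset_mean <- function(cond_name) {
    cond <- trial_condition(cond_name, 4)
    mean(vapply(1:200, function(i) {
      simulate_eye_trace(cond, obs, seed = 5000 + i)$truth$onset_time_ms
    }, numeric(1)))
  }
  m1 <- onset_mean("pursuit_first_order")
  m2 <- onset_mean("pursuit_second_order")
  expect_gt(m2, m1)
  # Monte-Carlo means sit near the configured per-observer means
  expect_equal(m1, obs$conditions$pursuit_first_order$latency_mean_ms,
               tolerance = 0.05)
  expect_equal(m2, obs$conditions$pursuit_second_order$latency_mean_ms,
               tolerance = 0.05)
})

test_that("simulate_response matches its closed form", {
  cond <- trial_condition("pursuit_first_order", 3)
  veridical <- quiet_observer(set_gamma(quiet_params(), 1))
  expect_equal(simulate_response(cond, veridical, seed = 1), 2000)
  slow <- quiet_observer(set_gamma(quiet_params(), 0.9))
  expect_equal(simulate_response(cond, slow, seed = 1),
               500 + 1000 * 4.5 / 2.7, tolerance = 1e-9)
  fast <- quiet_observer(set_gamma(quiet_params(), 1.25))
  expect_equal(simulate_response(cond, fast, seed = 1) - 2000, -300,
               tolerance = 1e-9)
  expect_error(quiet_observer(set_gamma(quiet_params(), -1)), "gamma")
})

test_that("simulated constant-error SD converges to the analytic value", {
  p <- quiet_params()
  p$shared$timing_cv <- 0.1
  p$shared$motor_sd_ms <- 30
  p <- set_gamma(p, 1)
  obs <- quiet_observer(p)
  cond <- trial_condition("pursuit_first_order", 3)
  resp <- vapply(1:1000, function(i) {
    simulate_response(cond, obs, seed = 20000 + i)
  }, numeric(1))
  ce <- resp - 2000
  analytic_sd <- sqrt((1500 * 0.1)^2 + 30^2)
  expect_equal(sd(ce), analytic_sd, tolerance = 0.1)
  expect_equal(mean(ce), 0, tolerance = 3 * analytic_sd / sqrt(1000) / 1)
})

test_that("saccade counts per trial are Poisson with the configured rate", {
  p <- quiet_params(saccade_rate = 2)
  obs <- quiet_observer(p)
  cond <- trial_condition("pursuit_second_order", 4)
  counts <- vapply(1:2000, function(i) {
    length(simulate_eye_trace(cond, obs, seed = 30000 + i,
                              pretrial_ms = 1000)$truth$saccade_onsets_ms)
  }, numeric(1))
  span_s <- (500 - obs$conditions$pursuit_second_order$latency_mean_ms) / 1000
  lambda <- 2 * span_s
  # chi-square GOF, bins 0,1,2,>=3
  obs_counts <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
                  sum(counts >= 3))
  pr <- c(dpois(0:2, lambda), 1 - ppois(2, lambda))
  expected <- 2000 * pr
  stat <- sum((obs_counts - expected)^2 / expected)
  expect_lt(stat, qchisq(0.99, df = 3))
})

test_that("simulate_dataset is deterministic and sized |observers| x |trials|", {
  des <- build_session(n_per_cell = 1, n_blocks = 1, seed = 3)
  d1 <- simulate_dataset(n_observers = 2, design = des, seed = 11)
  d2 <- simulate_dataset(n_observers = 2, design = des, seed = 11)
  expect_equal(nrow(d1$trials), 18)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$traces, d2$traces)
  d3 <- simulate_dataset(n_observers = 2, design = des, seed = 12)
  expect_false(identical(d1$trials$response_ms, d3$trials$response_ms))
  # single observer, 9 trials
  d4 <- simulate_dataset(n_observers = 1, design = des, seed = 1)
  expect_equal(nrow(d4$trials), 9)
  expect_length(d4$traces, 9)
})

test_that("blink spans appear as NaN with the configured probability", {
  p <- quiet_params(blink_prob = 1)
  obs <- quiet_observer(p)
  st <- simulate_eye_trace(trial_condition("fixation", 3), obs, seed = 9)
  expect_equal(nrow(st$truth$blink_spans_ms), 1)
  expect_true(any(!st$trace$valid))
  expect_true(all(is.nan(st$trace$x_deg[!st$trace$valid])))
  dur <- sum(!st$trace$valid)
  expect_gte(dur, 100)
  expect_lte(dur, 300)
})
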