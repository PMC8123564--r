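test_that("central difference matches analytic derivatives", {
  t_s <- (0:999) / 1000
  expect_equal(differentiate_central(3 * t_s * 1000 / 1000)[2:999] * 0,
               rep(0, 998)) # no NA introduced
  v <- differentiate_central(3 * t_s) # 3 deg/s ramp sampled at 1 ms
  expect_equal(v, rep(3, 1000), tolerance = 1e-9)
  expect_equal(differentiate_central(rep(2.5, 100)), rep(0, 100))
  x <- sin(2 * pi * 2 * t_s)
  v <- differentiate_central(x)
  expected <- 4 * pi * cos(2 * pi * 2 * t_s)
  interior <- 2:999
  expect_lt(max(abs(v[interior] - expected[interior]) / max(abs(expected))),
            0.001)
  expect_error(differentiate_central(c(1, 2)), "3 samples")
  # NaN propagation through the stencil
  x[500] <- NaN
  v <- differentiate_central(x)
  expect_true(all(is.nan(v[c(499, 501)])))
  expect_false(anyNA(v[c(497, 503)]))
})

test_that("FIR low-pass has unit DC gain, passes 10 Hz, kills 100 Hz", {
  h <- fir_lowpass_coefs()
  expect_length(h, 80)
  expect_equal(sum(h), 1)
  expect_equal(fir_lowpass(rep(4.2, 500)), rep(4.2, 500))
  t_s <- (0:1999) / 1000
  mid <- 500:1500
  g10 <- max(abs(fir_lowpass(sin(2 * pi * 10 * t_s))[mid]))
  expect_gt(g10, 0.95)
  g100 <- max(abs(fir_lowpass(sin(2 * pi * 100 * t_s))[mid]))
  expect_lt(g100, 0.1)
  expect_error(fir_lowpass(rnorm(80)), "longer")
  # impulse: one causal pass has support exactly n_taps
  imp <- c(1, numeric(200))
  y <- pursuitTTC:::conv_full(imp, h)
  expect_equal(sum(abs(y) > 0), 80)
  # zero phase: a smooth pulse is not shifted
  pulse <- exp(-((t_s - 1)^2) / (2 * 0.05^2))
  expect_equal(which.max(fir_lowpass(pulse)), which.max(pulse))
})

test_that("NaN spans pass through the filter untouched", {
  t_s <- (0:1999) / 1000
  x <- sin(2 * pi * 5 * t_s)
  x[300:420] <- NaN
  y <- fir_lowpass(x)
  expect_true(all(is.nan(y[300:420])))
  expect_false(anyNA(y[-(300:420)]))
  # single-pass mode also preserves NaN and the DC level
  y2 <- fir_lowpass(x, mode = "single_pass")
  expect_true(all(is.nan(y2[300:420])))
  expect_equal(fir_lowpass(rep(1.5, 300), mode = "single_pass"),
               rep(1.5, 300), tolerance = 1e-6)
})

test_that("detect_saccades equals the sample-by-sample oracle on random traces", {
  # the full 500-trace comparison lives in test-acceptance.R; this is a
  # quick regression guard
  set.seed(101)
  for (rep in 1:60) {
    n <- 400
    v <- rnorm(n, 0, 10)
    a <- rnorm(n, 0, 300)
    # sprinkle occasional pulses so events exist
    if (rep %% 2 == 0) {
      i <- sample(50:350, 1)
      v[i:(i + 5)] <- 45 * sign(rnorm(1))
    }
    if (rep %% 3 == 0) {
      i <- sample(50:350, 1)
      a[i:(i + 3)] <- 1500 * sign(rnorm(1))
    }
    got <- detect_saccades(v, a, t_ms = seq_len(n) - 1)
    want <- oracle_saccade_spans(v, a)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$onset_ms, want[, 1] - 1)
      expect_equal(got$offset_ms, want[, 2] - 1)
    }
  }
})

test_that("trigger annotation reflects which criterion fired", {
  n <- 300
  t_ms <- seq_len(n) - 1
  v <- rep(3, n); a <- numeric(n)
  expect_equal(nrow(detect_saccades(rep(20, n), a, t_ms)), 0)
  v2 <- v; v2[100:110] <- 40
  ev <- detect_saccades(v2, a, t_ms)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$trigger, "velocity")
  a2 <- a; a2[200:205] <- 1500
  v3 <- v; v3[200:205] <- 25
  ev2 <- detect_saccades(v3, a2, t_ms)
  expect_equal(ev2$trigger, "acceleration")
  expect_equal(ev2$peak_velocity, 25)
})

test_that("desaccade NaNs exactly the padded interval union", {
  n <- 500
  t_ms <- seq_len(n) - 1
  x <- rnorm(n)
  expect_identical(desaccade(x, t_ms, NULL), x)
  ev <- data.frame(onset_ms = 200, offset_ms = 230)
  y <- desaccade(x, t_ms, ev, pad_ms = 10)
  expect_true(all(is.nan(y[t_ms >= 190 & t_ms <= 240])))
  expect_identical(y[t_ms < 190 | t_ms > 240], x[t_ms < 190 | t_ms > 240])
  # property: random overlapping events == interval-union oracle
  set.seed(202)
  for (rep in 1:50) {
    k <- sample(1:6, 1)
    on <- sort(sample(20:450, k))
    off <- pmin(on + sample(5:60, k, replace = TRUE), n - 1)
    ev <- data.frame(onset_ms = on, offset_ms = off)
    y <- desaccade(x, t_ms, ev, pad_ms = 10)
    mask <- oracle_union_mask(n, on + 1, off + 1, pad = 10)
    expect_identical(is.nan(y), mask)
  }
})

test_that("detect_blinks finds dilated invalid runs", {
  tr <- data.frame(t_ms = 0:999, valid = TRUE)
  expect_equal(nrow(detect_blinks(tr)), 0)
  tr$valid[300:449] <- FALSE
  b <- detect_blinks(tr, guard_ms = 10)
  expect_equal(nrow(b), 1)
  expect_lte(b$onset_ms, 300)
  expect_gte(b$offset_ms, 449)
  # two spans separated by more than twice the guard stay distinct
  tr2 <- data.frame(t_ms = 0:999, valid = TRUE)
  tr2$valid[100:150] <- FALSE
  tr2$valid[400:430] <- FALSE
  expect_equal(nrow(detect_blinks(tr2, guard_ms = 10)), 2)
})

test_that("qc_trial applies the three exclusion rules", {
  geom <- stimulus_geometry()
  mk_trace <- function(x_fun) {
    t_ms <- -500:800
    data.frame(t_ms = t_ms, x_deg = x_fun(t_ms), y_deg = 0,
               valid = TRUE)
  }
  no_ev <- detect_saccades(numeric(10), numeric(10), 0:9)
  no_bl <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0))
  fix <- trial_condition("fixation", 3)
  # 3-deg excursion during presentation
  tr <- mk_trace(function(t) ifelse(t > 200 & t < 300, 0, -3))
  qc <- qc_trial(tr, fix, no_ev, no_bl, geom)
  expect_false(qc$keep)
  expect_equal(qc$reasons, "fixation_excursion")
  # clean fixation trial
  qc2 <- qc_trial(mk_trace(function(t) rep(-3, length(t))), fix, no_ev,
                  no_bl, geom)
  expect_true(qc2$keep)
  expect_length(qc2$reasons, 0)
  # pursuit saccade landing near the stationary object
  pur <- trial_condition("pursuit_first_order", 3)
  ev <- data.frame(onset_ms = 250, offset_ms = 280, trigger = "velocity",
                   peak_velocity = 100, start_deg = -1, landing_deg = 2.7)
  qc3 <- qc_trial(mk_trace(function(t) rep(-3, length(t))), pur, ev, no_bl,
                  geom)
  expect_false(qc3$keep)
  expect_equal(qc3$reasons, "saccade_to_target")
  # same landing but before presentation: kept
  ev$onset_ms <- -100; ev$offset_ms <- -70
  expect_true(qc_trial(mk_trace(function(t) rep(-3, length(t))), pur, ev,
                       no_bl, geom)$keep)
  # blink intersecting presentation excludes any condition
  bl <- data.frame(onset_ms = 480, offset_ms = 600)
  qc4 <- qc_trial(mk_trace(function(t) rep(-3, length(t))), fix, no_ev, bl,
                  geom)
  expect_false(qc4$keep)
  expect_equal(qc4$reasons, "blink")
})

test_that("average_traces is NaN-aware per sample", {
  a <- c(1, 2, 3, NaN)
  b <- c(3, NaN, 5, NaN)
  avg <- average_traces(list(a, b))
  expect_equal(avg$mean, c(2, 2, 4, NaN))
  expect_equal(avg$count, c(2, 1, 2, 0))
  ident <- average_traces(list(a, a))
  expect_equal(ident$sd[1:3], c(0, 0, 0))
  # min_count drops thin samples
  avg2 <- average_traces(list(a, b), min_count = 2)
  expect_true(is.nan(avg2$mean[2]))
  expect_error(average_traces(list()), "length")
})

test_that("saccade detection on simulated traces: full sensitivity, no false alarms", {
  p <- quiet_params(saccade_rate = 2)
  obs <- quiet_observer(p)
  n_events_total <- 0
  for (i in 1:120) {
    cond <- trial_condition(
      c("pursuit_first_order", "pursuit_second_order")[1 + i %% 2], 3 + i %% 3)
    st <- simulate_eye_trace(cond, obs, seed = 40000 + i, pretrial_ms = 1100)
    pre <- preprocess_trial(st$trace, cond)
    truth <- st$truth$saccade_onsets_ms
    n_events_total <- n_events_total + length(truth)
    if (length(truth) > 0) {
      # sensitivity: every true saccade onset falls inside a detected event
      covered <- vapply(truth, function(ts) {
        any(pre$events$onset_ms - 15 <= ts + 30 &
              pre$events$offset_ms + 15 >= ts)
      }, logical(1))
      expect_true(all(covered))
    }
    # specificity: every detected event contains a true saccade
    if (nrow(pre$events) > 0) {
      hit <- vapply(seq_len(nrow(pre$events)), function(k) {
        any(truth >= pre$events$onset_ms[k] - 45 &
              truth <= pre$events$offset_ms[k] + 15)
      }, logical(1))
      expect_true(all(hit))
    }
  }
  expect_gt(n_events_total, 50) # the property actually exercised events
})

test_that("noise-free clean dataset passes QC completely", {
  p <- quiet_params(saccade_rate = 1.5)
  des <- build_session(n_per_cell = 2, n_blocks = 1, seed = 5)
  ds <- simulate_dataset(n_observers = 1, design = des, seed = 6,
                         params = p)
  prep <- preprocess_dataset(ds)
  expect_true(all(prep$qc$keep))
})
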