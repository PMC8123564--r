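# Shared fixture builders: all fixtures are generated in code.

# Population parameters with every noise source switched off.
quiet_params <- function(latency_first = 130, latency_second = 160,
                         accel_first = 25, accel_second = 20,
                         gain_first = 0.95, gain_second = 0.75,
                         saccade_rate = 0, blink_prob = 0) {
  p <- default_sim_params()
  tweak <- function(cp, lat, acc, gain) {
    if (!is.null(cp$latency_mean_ms)) {
      cp$latency_mean_ms <- lat
      cp$latency_sd_ms <- 0
      cp$accel_mean <- acc
      cp$pursuit_gain <- gain
    }
    cp$saccade_rate_hz <- if (is.null(cp$latency_mean_ms)) 0 else saccade_rate
    cp$blink_prob <- blink_prob
    cp
  }
  p$conditions$pursuit_first_order <-
    tweak(p$conditions$pursuit_first_order, latency_first, accel_first,
          gain_first)
  p$conditions$pursuit_second_order <-
    tweak(p$conditions$pursuit_second_order, latency_second, accel_second,
          gain_second)
  p$conditions$fixation$blink_prob <- blink_prob
  p$shared$fixation_noise_sd_deg <- 0
  p$shared$timing_cv <- 0
  p$shared$motor_sd_ms <- 0
  p$between_observer <- list(latency_sd_ms = 0, accel_cv = 0, gain_sd = 0,
                             gamma_cv = 0, saccade_rate_cv = 0)
  p
}

# Override one perceptual gain everywhere (all conditions, all velocities).
set_gamma <- function(params, gamma) {
  for (cn in names(params$conditions)) {
    params$conditions[[cn]]$gamma <-
      lapply(params$conditions[[cn]]$gamma, function(g) gamma)
  }
  params
}

quiet_observer <- function(condition_params = quiet_params(), seed = 1) {
  sim_observer("t", condition_params, seed = seed)
}
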