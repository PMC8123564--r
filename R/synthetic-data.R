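#' Default synthetic-observer parameter set
#'
#' Reads the versioned simulator configuration shipped with the package.
#' Condition-level entries give pursuit latency (mean/SD, ms), initial eye
#' acceleration (deg/s^2), pursuit gain, catch-up saccade rate (1/s), blink
#' probability per trial, and the perceptual velocity gain `gamma` per object
#' velocity; `shared` entries give positional noise, scalar-timing CV, motor
#' SD, the post-occlusion velocity decay constant, and saccade/blink shape
#' parameters; `between_observer` gives the population spread used when
#' drawing individual observers.
#'
#' @param path Optional path to an alternative JSON parameter file.
#' @return Nested list of simulator parameters (class `sim_params`).
#' @export
default_sim_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "simulator-defaults.json",
                        package = "pursuitTTC")
  }
  stopifnot(nzchar(path), file.exists(path))
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  class(p) <- "sim_params"
  p
}

#' Draw one synthetic observer from the population
#'
#' Individual observers differ from the condition-level means by Gaussian
#' between-observer offsets (latency), multiplicative jitter (acceleration,
#' saccade rate, perceptual gain gamma) and additive jitter on pursuit gain,
#' clipped to physiological bounds (0 < gain <= 1.2, gamma > 0).
#'
#' @param observer_id Integer or character label.
#' @param params A [default_sim_params()] list.
#' @param seed Integer seed for this observer's parameter draw.
#' @return A `sim_observer` list with one parameter block per condition plus
#'   the shared noise parameters.
#' @export
sim_observer <- function(observer_id, params = default_sim_params(),
                         seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  shr <- params$shared
  bo <- params$between_observer
  conds <- with_seed(seed, {
    lapply(params$conditions, function(cp) {
      gam <- unlist(cp$gamma)
      if (any(gam <= 0)) stop("configured perceptual gain gamma must be > 0")
      gam <- gam * (1 + stats::rnorm(length(gam), 0, bo$gamma_cv))
      gam <- pmax(gam, 0.05)
      out <- list(
        gamma = as.list(gam),
        saccade_rate_hz = max(
          0, cp$saccade_rate_hz * (1 + stats::rnorm(1, 0, bo$saccade_rate_cv))),
        blink_prob = cp$blink_prob)
      if (!is.null(cp$latency_mean_ms)) {
        out$latency_mean_ms <- max(
          60, cp$latency_mean_ms + stats::rnorm(1, 0, bo$latency_sd_ms))
        out$latency_sd_ms <- cp$latency_sd_ms
        out$accel_mean <- max(
          5, cp$accel_mean * (1 + stats::rnorm(1, 0, bo$accel_cv)))
        out$pursuit_gain <- min(
          1.2, max(0.2, cp$pursuit_gain + stats::rnorm(1, 0, bo$gain_sd)))
      }
      out
    })
  })
  structure(
    c(list(observer_id = observer_id, conditions = conds), shr),
    class = "sim_observer")
}

# Per-(condition, velocity) parameter lookup on a sim_observer.
obs_param <- function(observer, condition, field, velocity = NULL) {
  cp <- observer$conditions[[condition]]
  if (is.null(cp)) stop("unknown condition: ", condition)
  val <- cp[[field]]
  if (!is.null(velocity) && is.list(val)) {
    val <- val[[as.character(velocity)]]
    if (is.null(val)) stop("no ", field, " for velocity ", velocity)
  }
  val
}

# Minimum-jerk displacement profile, 0 -> amplitude over n samples.
min_jerk_profile <- function(amplitude, n) {
  tau <- seq_len(n) / n
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Simulate one 1-kHz eye-position trace with ground truth
#'
#' Pursuit conditions: the eye fixates the left object (positional Gaussian
#' noise only) until a latency drawn from the observer's condition
#' parameters, accelerates linearly at the observer's initial acceleration up
#' to `pursuit_gain * velocity`, holds that steady-state velocity through
#' occlusion onset, and decays exponentially afterwards. Catch-up saccades
#' are 30-ms minimum-jerk position steps toward the instantaneous tracking
#' error (with a minimum amplitude so each is detectable by the
#' velocity/acceleration criteria), injected at Poisson times over the
#' pursuit epoch. Blinks are NaN spans with per-trial probability. The
#' fixation condition yields a noise-only trace around the gazed stationary
#' object.
#'
#' @param condition A [trial_condition()].
#' @param observer A [sim_observer()].
#' @param seed Integer seed for this trial.
#' @param pretrial_ms Pretrial fixation duration (ms before motion onset).
#' @param geometry A [stimulus_geometry()].
#' @param tmax_ms Trace end time (ms after motion onset).
#' @return A list with `trace` (data.frame `t_ms`, `x_deg`, `y_deg`,
#'   `valid`) and `truth` (onset_time_ms, steady_velocity, saccade_onsets_ms,
#'   blink_spans_ms, latency draw and per-trial parameters used).
#' @export
simulate_eye_trace <- function(condition, observer, seed,
                               pretrial_ms = 1200,
                               geometry = stimulus_geometry(),
                               tmax_ms = NULL) {
  stopifnot(inherits(condition, "trial_condition"),
            inherits(observer, "sim_observer"))
  if (is.null(tmax_ms)) tmax_ms <- observer$trace_tmax_ms
  dt <- 1 # ms, 1 kHz
  t_ms <- seq(-round(pretrial_ms), tmax_ms, by = dt)
  n <- length(t_ms)
  occl <- geometry$presentation_duration
  gaze0 <- -geometry$eccentricity # left object
  cond <- condition$visual_condition
  pursuing <- cond != "fixation"
  noise_sd <- observer$fixation_noise_sd_deg

  with_seed(seed, {
    truth <- list(onset_time_ms = NA_real_, steady_velocity = 0,
                  saccade_onsets_ms = numeric(0),
                  blink_spans_ms = matrix(numeric(0), ncol = 2))
    # Slow-phase eye velocity (deg/s) on the sample grid
    v_eye <- numeric(n)
    if (pursuing) {
      lat_mu <- obs_param(observer, cond, "latency_mean_ms")
      lat_sd <- obs_param(observer, cond, "latency_sd_ms")
      accel <- obs_param(observer, cond, "accel_mean")
      gain <- obs_param(observer, cond, "pursuit_gain")
      latency <- if (lat_sd > 0) max(60, stats::rnorm(1, lat_mu, lat_sd)) else lat_mu
      v_ss <- gain * condition$velocity
      truth$onset_time_ms <- latency
      truth$steady_velocity <- v_ss
      truth$initial_accel <- accel
      ramp <- pmin(pmax((t_ms - latency) / 1000 * accel, 0), v_ss)
      v_at_occl <- min(max((occl - latency) / 1000 * accel, 0), v_ss)
      tau <- observer$post_occlusion_tau_ms
      post <- t_ms > occl
      ramp[post] <- v_at_occl * exp(-(t_ms[post] - occl) / tau)
      v_eye <- ramp * condition$motion_direction
    }
    x <- gaze0 + cumsum(v_eye) * dt / 1000

    # Catch-up saccades: Poisson times on [onset, occlusion], refractory-thinned
    rate <- obs_param(observer, cond, "saccade_rate_hz")
    if (pursuing && rate > 0) {
      span0 <- truth$onset_time_ms
      span <- occl - span0
      if (span > 0) {
        # exact Poisson count over the pursuit epoch; overlapping saccades
        # superpose (and may merge into one detected event downstream)
        k <- stats::rpois(1, rate * span / 1000)
        times <- sort(stats::runif(k, span0, occl))
        dur <- round(observer$saccade_duration_ms)
        for (ts in times) {
          i0 <- which.min(abs(t_ms - ts))
          if (i0 + dur > n) next
          # target position along the motion axis at saccade onset
          tgt <- gaze0 + condition$motion_direction *
            (condition$velocity * min(t_ms[i0], occl) / 1000 -
               condition$velocity * 0.1)
          err <- tgt - x[i0]
          amp <- sign(ifelse(err == 0, condition$motion_direction, err)) *
            max(abs(err), observer$saccade_min_amplitude_deg)
          prof <- min_jerk_profile(amp, dur)
          idx <- (i0 + 1):(i0 + dur)
          x[idx] <- x[idx] + prof
          if (i0 + dur < n) x[(i0 + dur + 1):n] <- x[(i0 + dur + 1):n] + amp
          truth$saccade_onsets_ms <- c(truth$saccade_onsets_ms, t_ms[i0])
        }
      }
    }

    if (noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, noise_sd)
      y <- stats::rnorm(n, 0, noise_sd)
    } else {
      y <- numeric(n)
    }

    valid <- rep(TRUE, n)
    blink_p <- obs_param(observer, cond, "blink_prob")
    if (blink_p > 0 && stats::runif(1) < blink_p) {
      rng <- observer$blink_duration_range_ms
      bdur <- round(stats::runif(1, rng[1], rng[2]))
      b0 <- round(stats::runif(1, t_ms[1], tmax_ms - bdur))
      bi <- which(t_ms >= b0 & t_ms < b0 + bdur)
      valid[bi] <- FALSE
      x[bi] <- NaN
      y[bi] <- NaN
      truth$blink_spans_ms <- rbind(truth$blink_spans_ms,
                                    c(b0, b0 + bdur - 1))
    }

    trace <- data.frame(t_ms = t_ms, x_deg = x, y_deg = y, valid = valid)
    list(trace = trace, truth = truth)
  })
}

#' Simulate one time-to-contact button response
#'
#' The synthetic observer extrapolates the occluded motion with a perceptual
#' velocity gain `gamma` and scalar (Weber-like, multiplicative) timing
#' noise, then adds Gaussian motor noise:
#' `response = occlusion + remaining/(gamma*v) * (1 + e_cv) + e_motor`,
#' where `remaining = separation - v * presentation_duration` (deg, the
#' occluded distance) and times are ms from motion onset. gamma > 1 produces
#' early responses (negative constant error), gamma < 1 late ones.
#'
#' @param condition A [trial_condition()].
#' @param observer A [sim_observer()].
#' @param seed Integer seed.
#' @param geometry A [stimulus_geometry()].
#' @return Response time in ms from motion onset (always after occlusion;
#'   non-positive occluded intervals are redrawn, which is vanishingly rare
#'   at the default noise levels).
#' @export
simulate_response <- function(condition, observer, seed,
                              geometry = stimulus_geometry()) {
  stopifnot(inherits(condition, "trial_condition"),
            inherits(observer, "sim_observer"))
  v <- condition$velocity
  gam <- obs_param(observer, condition$visual_condition, "gamma", v)
  if (is.null(gam) || gam <= 0) stop("perceptual gain gamma must be > 0")
  occl <- geometry$presentation_duration
  remaining <- geometry$separation - v * occl / 1000 # deg still to cover
  mean_occluded <- 1000 * remaining / (gam * v)      # ms
  with_seed(seed, {
    for (i in 1:100) {
      rt <- mean_occluded * (1 + stats::rnorm(1, 0, observer$timing_cv)) +
        stats::rnorm(1, 0, observer$motor_sd_ms)
      if (rt > 0) break
    }
    occl + max(rt, 1)
  })
}

#' Simulate a full multi-observer dataset
#'
#' One simulated trial (eye trace + button response + ground truth) per
#' (observer, session-design trial). Per-trial seeds are derived
#' deterministically from the master seed, so the same seed reproduces the
#' dataset exactly.
#'
#' @param n_observers Number of observers to draw (default 12), or a list of
#'   pre-built [sim_observer()] objects via `observers`.
#' @param design A [build_session()] design (shared by all observers).
#' @param seed Master integer seed.
#' @param params Population parameters for observer draws.
#' @param geometry A [stimulus_geometry()].
#' @param observers Optional explicit list of observers (overrides
#'   `n_observers`/`params`).
#' @return A `sim_dataset` list: `trials` (one row per simulated trial with
#'   observer_id, the design columns, `response_ms` and scalar truth
#'   columns), `traces` (list of trace data.frames, named
#'   "<observer>_<trial_id>"), `truth` (list of full truth annotations),
#'   `observers`, `design`, `geometry`, `seed`.
#' @export
simulate_dataset <- function(n_observers = 12, design = build_session(),
                             seed = 1L, params = default_sim_params(),
                             geometry = stimulus_geometry(),
                             observers = NULL) {
  stopifnot(inherits(design, "session_design"))
  if (is.null(observers)) {
    stopifnot(n_observers >= 1)
    observers <- lapply(seq_len(n_observers), function(i) {
      sim_observer(i, params, seed = derive_seed(seed, 1000 + i))
    })
  }
  stopifnot(length(observers) >= 1)
  rows <- vector("list", length(observers) * nrow(design))
  traces <- vector("list", length(rows))
  truths <- vector("list", length(rows))
  keys <- character(length(rows))
  k <- 0
  for (oi in seq_along(observers)) {
    obs <- observers[[oi]]
    for (ti in seq_len(nrow(design))) {
      k <- k + 1
      cond <- trial_condition(design$visual_condition[ti], design$velocity[ti])
      st <- simulate_eye_trace(
        cond, obs, seed = derive_seed(seed, oi, ti, 1),
        pretrial_ms = design$pretrial_ms[ti], geometry = geometry)
      resp <- simulate_response(cond, obs,
                                seed = derive_seed(seed, oi, ti, 2),
                                geometry = geometry)
      rows[[k]] <- data.frame(
        observer_id = obs$observer_id,
        trial_id = design$trial_id[ti],
        block = design$block[ti],
        visual_condition = design$visual_condition[ti],
        velocity = design$velocity[ti],
        pretrial_ms = design$pretrial_ms[ti],
        response_ms = resp,
        truth_onset_ms = st$truth$onset_time_ms,
        truth_steady_vel = st$truth$steady_velocity,
        n_truth_saccades = length(st$truth$saccade_onsets_ms),
        has_blink = nrow(st$truth$blink_spans_ms) > 0)
      traces[[k]] <- st$trace
      truths[[k]] <- st$truth
      keys[k] <- paste0(obs$observer_id, "_", design$trial_id[ti])
    }
  }
  names(traces) <- keys
  names(truths) <- keys
  structure(
    list(trials = do.call(rbind, rows), traces = traces, truth = truths,
         observers = observers, design = design, geometry = geometry,
         seed = seed),
    class = "sim_dataset")
}
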