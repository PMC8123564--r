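#' Pretrial baseline velocity statistics
#'
#' NaN-aware mean and SD of eye velocity over a pretrial fixation window,
#' used for the 3-SD pursuit-onset threshold.
#'
#' @param velocity Velocity series (deg/s).
#' @param t_ms Time stamps (ms, 0 = motion onset).
#' @param window Two-element window in ms (default c(-300, 0)).
#' @return List with `mean` and `sd`.
#' @export
pretrial_baseline <- function(velocity, t_ms, window = c(-300, 0)) {
  idx <- t_ms >= window[1] & t_ms < window[2]
  v <- velocity[idx]
  if (all(!is.finite(v))) stop("pretrial baseline window is all-NaN")
  list(mean = nan_mean(v), sd = if (sum(is.finite(v)) > 1) nan_sd(v) else 0)
}

#' Pursuit onset time from an averaged velocity trace
#'
#' The earliest time `t >= 0` at which the velocity component in the motion
#' direction exceeds `baseline$mean + 3 * baseline$sd` continuously for
#' `sustain_ms`. The sustain criterion suppresses single-sample noise
#' crossings. A degenerate baseline (sd = 0) falls back to a configurable
#' absolute floor on the threshold.
#'
#' @param velocity Velocity series (deg/s), signed.
#' @param t_ms Time stamps (ms, 0 = motion onset).
#' @param baseline List from [pretrial_baseline()].
#' @param motion_direction +1 rightward, -1 leftward; velocity is projected
#'   onto this direction before thresholding.
#' @param n_sd Number of baseline SDs above the mean (default 3).
#' @param sustain_ms Required continuous supra-threshold time (default 20).
#' @param threshold_floor Minimum threshold height above the baseline mean
#'   (deg/s, default 0.2) for degenerate noise-free baselines.
#' @return Onset time in ms, or NA if the criterion is never met.
#' @export
pursuit_onset <- function(velocity, t_ms, baseline, motion_direction = 1,
                          n_sd = 3, sustain_ms = 20, threshold_floor = 0.2) {
  stopifnot(baseline$sd >= 0 || is.na(baseline$sd))
  sdv <- if (is.finite(baseline$sd)) baseline$sd else 0
  thr <- baseline$mean + max(n_sd * sdv, threshold_floor)
  v_dir <- velocity * motion_direction
  dt <- t_ms[2] - t_ms[1]
  need <- max(1, round(sustain_ms / dt))
  post <- which(t_ms >= 0)
  above <- v_dir[post] > thr
  above[is.na(above)] <- FALSE
  runs <- true_runs(above)
  runs <- runs[runs$end - runs$start + 1 >= need, , drop = FALSE]
  if (nrow(runs) == 0) return(NA_real_)
  t_ms[post[runs$start[1]]]
}

#' Pursuit latency
#'
#' Time lapse between motion onset and pursuit onset.
#'
#' @param onset_time_ms Onset from [pursuit_onset()] (ms).
#' @param motion_onset_ms Motion onset (default 0).
#' @return Latency in ms (NA if onset absent).
#' @export
pursuit_latency <- function(onset_time_ms, motion_onset_ms = 0) {
  onset_time_ms - motion_onset_ms
}

#' Initial pursuit acceleration
#'
#' NaN-aware mean of the acceleration trace over the first `win_ms`
#' (default 100 ms) of smooth pursuit, i.e. `[onset, onset + win_ms)`.
#'
#' @param acceleration Acceleration series (deg/s^2), signed.
#' @param t_ms Time stamps (ms).
#' @param onset_time_ms Pursuit onset (ms).
#' @param motion_direction +1/-1; the result is reported along the motion
#'   direction (positive = accelerating toward the target motion).
#' @param win_ms Window length (default 100).
#' @return List with `value` (deg/s^2) and `low_confidence` (TRUE when more
#'   than half of the window is NaN).
#' @export
initial_acceleration <- function(acceleration, t_ms, onset_time_ms,
                                 motion_direction = 1, win_ms = 100) {
  if (!is.finite(onset_time_ms)) {
    return(list(value = NA_real_, low_confidence = TRUE))
  }
  idx <- t_ms >= onset_time_ms & t_ms < onset_time_ms + win_ms
  if (!any(idx)) stop("acceleration window lies outside the trace")
  a <- acceleration[idx] * motion_direction
  list(value = nan_mean(a),
       low_confidence = mean(!is.finite(a)) > 0.5)
}

#' Steady-state pursuit velocity
#'
#' NaN-aware mean of the desaccaded velocity over a late presentation
#' window, reported along the motion direction.
#'
#' @param velocity Desaccaded velocity series (deg/s), signed.
#' @param t_ms Time stamps (ms).
#' @param window Analysis window in ms (default c(300, 500)); a documented
#'   choice, not a measured fact of the paradigm.
#' @param motion_direction +1/-1.
#' @return Mean velocity in deg/s, NA if the window is fully NaN.
#' @export
steady_state_velocity <- function(velocity, t_ms, window = c(300, 500),
                                  motion_direction = 1) {
  idx <- t_ms >= window[1] & t_ms < window[2]
  v <- velocity[idx] * motion_direction
  nan_mean(v)
}

#' Saccade rate over the presentation periods
#'
#' Number of saccades with onset inside the presentation period, divided by
#' the total presentation time across trials.
#'
#' @param n_events Total count of presentation-period saccade onsets.
#' @param total_duration_ms Total presentation duration summed over trials.
#' @return Rate in events/s.
#' @export
saccade_rate <- function(n_events, total_duration_ms) {
  if (total_duration_ms <= 0) stop("total duration must be positive")
  1000 * n_events / total_duration_ms
}

#' Pursuit metrics for a set of preprocessed trials
#'
#' Averages the trials' desaccaded velocity (and acceleration) traces
#' aligned at motion onset, then measures onset, latency, initial
#' acceleration, steady-state velocity, and the saccade rate, as done per
#' (condition, velocity) cell.
#'
#' @param pre_trials List of [preprocess_trial()] results (same condition).
#' @param condition The shared [trial_condition()].
#' @param geometry A [stimulus_geometry()].
#' @param baseline_window,ss_window,sustain_ms,accel_win_ms Analysis windows.
#' @return One-row data.frame: onset_ms, latency_ms, init_accel,
#'   ss_velocity, saccade_rate_hz, n_trials.
#' @export
pursuit_metrics_cell <- function(pre_trials, condition,
                                 geometry = stimulus_geometry(),
                                 baseline_window = c(-300, 0),
                                 ss_window = c(300, 500),
                                 sustain_ms = 20, accel_win_ms = 100) {
  stopifnot(length(pre_trials) >= 1)
  # Align on a common motion-onset grid (pretrial jitter gives traces
  # different lengths; crop to the shared [-min_pre, tmax] span).
  t0 <- max(vapply(pre_trials, function(p) p$t_ms[1], numeric(1)))
  t1 <- min(vapply(pre_trials, function(p) p$t_ms[length(p$t_ms)], numeric(1)))
  crop <- function(p, what) {
    keep <- p$t_ms >= t0 & p$t_ms <= t1
    p[[what]][keep]
  }
  t_ms <- seq(t0, t1, by = pre_trials[[1]]$t_ms[2] - pre_trials[[1]]$t_ms[1])
  avg_v <- average_traces(lapply(pre_trials, crop, "velocity_desacc"))
  avg_a <- average_traces(lapply(pre_trials, crop, "acceleration_desacc"))
  bl <- pretrial_baseline(avg_v$mean, t_ms, baseline_window)
  onset <- pursuit_onset(avg_v$mean, t_ms, bl,
                         motion_direction = condition$motion_direction,
                         sustain_ms = sustain_ms)
  lat <- pursuit_latency(onset)
  acc <- initial_acceleration(avg_a$mean, t_ms, onset,
                              motion_direction = condition$motion_direction,
                              win_ms = accel_win_ms)
  ssv <- steady_state_velocity(avg_v$mean, t_ms, ss_window,
                               motion_direction = condition$motion_direction)
  pres <- geometry$presentation_duration
  n_sacc <- sum(vapply(pre_trials, function(p) {
    if (nrow(p$events) == 0) 0L
    else sum(p$events$onset_ms >= 0 & p$events$onset_ms <= pres)
  }, numeric(1)))
  data.frame(onset_ms = onset, latency_ms = lat, init_accel = acc$value,
             ss_velocity = ssv,
             saccade_rate_hz = saccade_rate(n_sacc,
                                            pres * length(pre_trials)),
             n_trials = length(pre_trials))
}
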