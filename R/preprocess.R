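#' Preprocessing options
#'
#' Bundles every tunable preprocessing decision. Defaults follow the
#' analysis contract: central-difference differentiation of raw position,
#' 80-tap 30-Hz FIR low-pass applied zero-phase (forward-backward) to
#' velocity, acceleration differentiated from the *filtered* velocity and
#' filtered again, saccade detection at 30 deg/s OR 1000 deg/s^2, saccade
#' spans padded +/-10 ms and merged across gaps under 20 ms.
#'
#' @param n_taps FIR length in taps (default 80).
#' @param passband_hz FIR passband edge in Hz (default 30).
#' @param fs_hz Sampling rate in Hz (default 1000).
#' @param filter_mode "zero_phase" (forward-backward, default) or
#'   "single_pass" (causal, one pass).
#' @param accel_from "filtered_velocity" (default) or "raw_velocity":
#'   which velocity series acceleration is differentiated from.
#' @param v_thr,a_thr Saccade velocity (deg/s) and acceleration (deg/s^2)
#'   thresholds.
#' @param pad_ms Desaccading pad on each side of an event (ms).
#' @param merge_gap_ms Events closer than this are fused (ms).
#' @param blink_guard_ms Dilation of tracker-loss spans on each side (ms).
#' @param excursion_limit_deg Fixation-condition exclusion limit (deg).
#' @param excursion_metric "horizontal" (default) or "euclidean".
#' @param capture_radius_deg Radius around the stationary object within
#'   which a saccade landing counts as "to the stationary object" (deg).
#' @return List of class `preprocess_options`.
#' @export
preprocess_options <- function(n_taps = 80, passband_hz = 30, fs_hz = 1000,
                               filter_mode = c("zero_phase", "single_pass"),
                               accel_from = c("filtered_velocity",
                                              "raw_velocity"),
                               v_thr = 30, a_thr = 1000,
                               pad_ms = 10, merge_gap_ms = 20,
                               blink_guard_ms = 10,
                               excursion_limit_deg = 2,
                               excursion_metric = c("horizontal", "euclidean"),
                               capture_radius_deg = 1.5) {
  structure(
    list(n_taps = n_taps, passband_hz = passband_hz, fs_hz = fs_hz,
         filter_mode = match.arg(filter_mode),
         accel_from = match.arg(accel_from),
         v_thr = v_thr, a_thr = a_thr, pad_ms = pad_ms,
         merge_gap_ms = merge_gap_ms, blink_guard_ms = blink_guard_ms,
         excursion_limit_deg = excursion_limit_deg,
         excursion_metric = match.arg(excursion_metric),
         capture_radius_deg = capture_radius_deg),
    class = "preprocess_options")
}

#' Central-difference differentiation
#'
#' `v[i] = (x[i+1] - x[i-1]) / (2 dt)` at interior samples, one-sided
#' differences at the endpoints. NaN inputs propagate to the samples whose
#' stencil touches them. Input in deg on a ms grid yields deg/s.
#'
#' @param x Position series (deg).
#' @param dt_ms Sample interval in ms (default 1).
#' @return Velocity series in deg/s, same length as `x`.
#' @export
differentiate_central <- function(x, dt_ms = 1) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  dt_s <- dt_ms / 1000
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt_s)
  v[1] <- (x[2] - x[1]) / dt_s
  v[n] <- (x[n] - x[n - 1]) / dt_s
  v
}

#' Linear-phase FIR low-pass coefficients (windowed sinc, Hamming)
#'
#' @param n_taps Number of taps (default 80).
#' @param passband_hz Passband edge / cutoff in Hz (default 30).
#' @param fs_hz Sampling rate in Hz (default 1000).
#' @return Numeric vector of `n_taps` coefficients, unit DC gain.
#' @export
fir_lowpass_coefs <- function(n_taps = 80, passband_hz = 30, fs_hz = 1000) {
  stopifnot(n_taps >= 2, passband_hz > 0, passband_hz < fs_hz / 2)
  m <- (n_taps - 1) / 2
  k <- seq_len(n_taps) - 1
  fc <- passband_hz / fs_hz # normalized cutoff (cycles/sample)
  arg <- 2 * pi * fc * (k - m)
  h <- ifelse(abs(k - m) < 1e-9, 2 * fc, sin(arg) / (pi * (k - m)))
  w <- 0.54 - 0.46 * cos(2 * pi * k / (n_taps - 1)) # Hamming
  h <- h * w
  h / sum(h) # unit DC gain
}

# Full linear convolution (length nx + nh - 1) via causal stats::filter.
conv_full <- function(x, h) {
  nh <- length(h)
  z <- c(numeric(nh - 1), x, numeric(nh - 1))
  y <- as.numeric(stats::filter(z, h, method = "convolution", sides = 1))
  y[nh:length(z)]
}

# Zero-phase (forward-backward) FIR on a fully finite segment.
filtfilt_fir <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  pad <- min(nh, n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]          # odd reflection
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  z <- c(left, x, right)
  y1 <- conv_full(z, h)
  y2 <- rev(conv_full(rev(y1), h))
  # combined group delay of the two passes is nh - 1 samples
  aligned <- y2[(nh):(nh + length(z) - 1)]
  aligned[(pad + 1):(pad + n)]
}

# Single-pass (causal, delay-compensated) FIR on a finite segment.
filt_once_fir <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  pad <- min(nh, n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  z <- c(left, x, right)
  y <- conv_full(z, h)
  delay <- (nh - 1) / 2
  idx <- pad + seq_len(n) + delay
  lo <- floor(idx); frac <- idx - lo
  y_lo <- y[lo]; y_hi <- y[pmin(lo + 1, length(y))]
  y_lo * (1 - frac) + y_hi * frac # half-sample delay of an even-tap FIR
}

#' Low-pass filter a series with the 80-tap 30-Hz FIR
#'
#' Applies the windowed-sinc FIR (see [fir_lowpass_coefs()]) zero-phase
#' (forward-backward) by default so event timing is not lag-shifted. NaN
#' spans are left untouched: each maximal finite segment is filtered
#' independently, and segments no longer than the filter are passed through
#' unchanged.
#'
#' @param x Series to filter.
#' @param n_taps,passband_hz,fs_hz Filter design parameters.
#' @param mode "zero_phase" (default) or "single_pass".
#' @return Filtered series, NaN exactly where the input was NaN.
#' @export
fir_lowpass <- function(x, n_taps = 80, passband_hz = 30, fs_hz = 1000,
                        mode = c("zero_phase", "single_pass")) {
  mode <- match.arg(mode)
  if (length(x) <= n_taps) stop("series must be longer than n_taps")
  h <- fir_lowpass_coefs(n_taps, passband_hz, fs_hz)
  out <- x
  runs <- true_runs(is.finite(x))
  apply_fun <- if (mode == "zero_phase") filtfilt_fir else filt_once_fir
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    if (length(idx) > n_taps) out[idx] <- apply_fun(x[idx], h)
  }
  out
}

#' Detect saccades by velocity/acceleration thresholds
#'
#' An event is a maximal run of samples where `|velocity| >= v_thr` OR
#' `|acceleration| >= a_thr`; runs separated by less than `merge_gap_ms` are
#' fused. Each event records its trigger ("velocity", "acceleration" or
#' "both"), peak absolute velocity, and — when a position series is supplied
#' — the start and landing positions.
#'
#' @param velocity Velocity series (deg/s).
#' @param acceleration Acceleration series (deg/s^2), same grid.
#' @param t_ms Time stamps (ms) of the samples.
#' @param position Optional position series (deg) for landing annotation.
#' @param v_thr,a_thr Thresholds (defaults 30 deg/s, 1000 deg/s^2).
#' @param merge_gap_ms Fuse events closer than this gap (default 20 ms).
#' @return data.frame with onset_ms, offset_ms, trigger, peak_velocity,
#'   start_deg, landing_deg (zero rows if no event).
#' @export
detect_saccades <- function(velocity, acceleration, t_ms,
                            position = NULL,
                            v_thr = 30, a_thr = 1000, merge_gap_ms = 20) {
  stopifnot(length(velocity) == length(acceleration),
            length(velocity) == length(t_ms))
  dt <- if (length(t_ms) > 1) t_ms[2] - t_ms[1] else 1
  hit <- (abs(velocity) >= v_thr) | (abs(acceleration) >= a_thr)
  runs <- true_runs(hit)
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      trigger = character(0), peak_velocity = numeric(0),
                      start_deg = numeric(0), landing_deg = numeric(0))
  if (nrow(runs) == 0) return(empty)
  runs <- merge_runs(runs, gap = max(1, round(merge_gap_ms / dt)))
  out <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    v_hit <- any(abs(velocity[idx]) >= v_thr, na.rm = TRUE)
    a_hit <- any(abs(acceleration[idx]) >= a_thr, na.rm = TRUE)
    data.frame(
      onset_ms = t_ms[runs$start[i]],
      offset_ms = t_ms[runs$end[i]],
      trigger = if (v_hit && a_hit) "both"
                else if (v_hit) "velocity" else "acceleration",
      peak_velocity = max(abs(velocity[idx]), na.rm = TRUE),
      start_deg = if (is.null(position)) NA_real_ else position[runs$start[i]],
      landing_deg = if (is.null(position)) NA_real_
                    else position[min(runs$end[i] + 1, length(position))])
  })
  do.call(rbind, out)
}

#' Replace saccadic samples with NaN
#'
#' Samples inside `[onset - pad_ms, offset + pad_ms]` of any event become
#' NaN; everything else is returned unchanged. Overlapping padded spans
#' merge naturally.
#'
#' @param x Series to desaccade (typically filtered velocity).
#' @param t_ms Time stamps (ms).
#' @param events Event table from [detect_saccades()].
#' @param pad_ms Pad on each side (default 10 ms).
#' @return `x` with NaN over the padded event spans.
#' @export
desaccade <- function(x, t_ms, events, pad_ms = 10) {
  if (is.null(events) || nrow(events) == 0) return(x)
  for (i in seq_len(nrow(events))) {
    x[t_ms >= events$onset_ms[i] - pad_ms &
        t_ms <= events$offset_ms[i] + pad_ms] <- NaN
  }
  x
}

#' Detect blink spans from the validity mask
#'
#' Blinks appear as tracker signal loss: runs of `valid == FALSE`. Each run
#' is dilated by `guard_ms` on both sides (the lids distort the signal just
#' before and after full loss) and overlapping dilated spans are merged.
#'
#' @param trace Trace data.frame with `t_ms` and `valid`.
#' @param guard_ms Guard margin per side (default 10 ms).
#' @return data.frame with onset_ms, offset_ms (zero rows if none).
#' @export
detect_blinks <- function(trace, guard_ms = 10) {
  runs <- true_runs(!trace$valid)
  if (nrow(runs) == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  t_ms <- trace$t_ms
  dt <- if (length(t_ms) > 1) t_ms[2] - t_ms[1] else 1
  g <- round(guard_ms / dt)
  runs$start <- pmax(1, runs$start - g)
  runs$end <- pmin(length(t_ms), runs$end + g)
  runs <- merge_runs(runs, gap = 1)
  data.frame(onset_ms = t_ms[runs$start], offset_ms = t_ms[runs$end])
}

#' Trial-level quality control
#'
#' Applies the exclusion rules: fixation trials are dropped when the eye
#' moves more than `excursion_limit_deg` (default +/-2 deg) from the gazed
#' object during the presentation period; pursuit trials are dropped when a
#' presentation-period saccade lands within `capture_radius_deg` of the
#' stationary object while moving toward it; any trial is dropped when a
#' blink span intersects the presentation period.
#'
#' @param trace Raw trace data.frame (`t_ms`, `x_deg`, `y_deg`, `valid`).
#' @param condition A [trial_condition()].
#' @param events Saccade table from [detect_saccades()] (with positions).
#' @param blinks Blink table from [detect_blinks()].
#' @param geometry A [stimulus_geometry()].
#' @param opts A [preprocess_options()].
#' @return List with `keep` (logical) and `reasons` (character subset of
#'   "fixation_excursion", "saccade_to_target", "blink"); `keep` is TRUE iff
#'   `reasons` is empty.
#' @export
qc_trial <- function(trace, condition, events, blinks,
                     geometry = stimulus_geometry(),
                     opts = preprocess_options()) {
  stopifnot(inherits(condition, "trial_condition"))
  pres <- c(0, geometry$presentation_duration)
  in_pres <- trace$t_ms >= pres[1] & trace$t_ms <= pres[2]
  reasons <- character(0)
  gaze0 <- -geometry$eccentricity

  if (condition$visual_condition == "fixation") {
    dx <- trace$x_deg[in_pres] - gaze0
    exc <- if (opts$excursion_metric == "euclidean") {
      sqrt(dx^2 + trace$y_deg[in_pres]^2)
    } else abs(dx)
    if (any(exc > opts$excursion_limit_deg, na.rm = TRUE)) {
      reasons <- c(reasons, "fixation_excursion")
    }
  } else if (!is.null(events) && nrow(events) > 0) {
    # stationary object sits opposite the gazed (left, moving) object
    target <- geometry$eccentricity
    ev <- events[events$onset_ms >= pres[1] & events$onset_ms <= pres[2], ,
                 drop = FALSE]
    if (nrow(ev) > 0 && !all(is.na(ev$landing_deg))) {
      toward <- (ev$landing_deg - ev$start_deg) * sign(target - ev$start_deg) > 0
      near <- abs(ev$landing_deg - target) <= opts$capture_radius_deg
      if (any(toward & near, na.rm = TRUE)) {
        reasons <- c(reasons, "saccade_to_target")
      }
    }
  }

  if (!is.null(blinks) && nrow(blinks) > 0 &&
      any(blinks$onset_ms <= pres[2] & blinks$offset_ms >= pres[1])) {
    reasons <- c(reasons, "blink")
  }

  list(keep = length(reasons) == 0, reasons = reasons)
}

#' Preprocess one trial end to end
#'
#' Runs the pipeline in the analysis order: differentiate position
#' (central difference) -> filter velocity -> differentiate to acceleration
#' (from filtered or raw velocity per `opts`) -> filter acceleration ->
#' detect saccades -> desaccade velocity -> detect blinks -> QC.
#'
#' @param trace Raw trace data.frame.
#' @param condition A [trial_condition()].
#' @param geometry A [stimulus_geometry()].
#' @param opts A [preprocess_options()].
#' @return List: `t_ms`, `velocity` (filtered), `velocity_desacc`,
#'   `acceleration`, `events`, `blinks`, `qc`, plus the input `trace`.
#' @export
preprocess_trial <- function(trace, condition,
                             geometry = stimulus_geometry(),
                             opts = preprocess_options()) {
  t_ms <- trace$t_ms
  dt <- t_ms[2] - t_ms[1]
  v_raw <- differentiate_central(trace$x_deg, dt_ms = dt)
  v_f <- fir_lowpass(v_raw, opts$n_taps, opts$passband_hz, opts$fs_hz,
                     mode = opts$filter_mode)
  a_src <- if (opts$accel_from == "filtered_velocity") v_f else v_raw
  a_raw <- differentiate_central(a_src, dt_ms = dt)
  a_f <- fir_lowpass(a_raw, opts$n_taps, opts$passband_hz, opts$fs_hz,
                     mode = opts$filter_mode)
  events <- detect_saccades(v_f, a_f, t_ms, position = trace$x_deg,
                            v_thr = opts$v_thr, a_thr = opts$a_thr,
                            merge_gap_ms = opts$merge_gap_ms)
  # one-sided endpoint derivatives can spike on noise; drop events that
  # touch the first/last two samples of the trace
  n <- length(t_ms)
  if (nrow(events) > 0) {
    events <- events[events$onset_ms > t_ms[2] &
                       events$offset_ms < t_ms[n - 1], , drop = FALSE]
  }
  v_d <- desaccade(v_f, t_ms, events, pad_ms = opts$pad_ms)
  # metrics-grade acceleration comes from the desaccaded velocity: the
  # saccade core never enters the differentiation, so no filter-ringing
  # tails leak past the masked span (they reach ~n_taps/2 beyond the event
  # when the spike itself is filtered)
  a_d <- desaccade(fir_lowpass(differentiate_central(v_d, dt_ms = dt),
                               opts$n_taps, opts$passband_hz, opts$fs_hz,
                               mode = opts$filter_mode),
                   t_ms, events, pad_ms = opts$pad_ms)
  blinks <- detect_blinks(trace, guard_ms = opts$blink_guard_ms)
  qc <- qc_trial(trace, condition, events, blinks, geometry, opts)
  list(t_ms = t_ms, velocity = v_f, velocity_desacc = v_d,
       acceleration = a_f, acceleration_desacc = a_d,
       events = events, blinks = blinks, qc = qc,
       trace = trace)
}

#' Average aligned velocity traces
#'
#' Per-sample NaN-aware mean and SD over trials aligned at motion onset.
#' Samples with fewer than `min_count` contributing trials are NaN.
#'
#' @param traces List of numeric vectors on a common grid.
#' @param min_count Minimum contributing trials per sample (default 1).
#' @return List with `mean`, `sd`, `count` vectors.
#' @export
average_traces <- function(traces, min_count = 1) {
  stopifnot(length(traces) >= 1)
  lens <- vapply(traces, length, integer(1))
  stopifnot(length(unique(lens)) == 1)
  m <- do.call(rbind, traces)
  fin <- is.finite(m)
  cnt <- colSums(fin)
  m[!fin] <- 0
  mu <- ifelse(cnt >= pmax(min_count, 1), colSums(m) / pmax(cnt, 1), NaN)
  # NaN-aware per-sample SD
  dev <- (sweep(do.call(rbind, traces), 2, mu))^2
  dev[!fin] <- 0
  sdv <- ifelse(cnt >= max(min_count, 2),
                sqrt(colSums(dev) / pmax(cnt - 1, 1)), NaN)
  list(mean = mu, sd = sdv, count = cnt)
}
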