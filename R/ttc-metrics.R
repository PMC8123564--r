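#' Constant error of a time-to-contact response
#'
#' `response_time - contact_time`, both on the motion-onset clock; negative
#' values are early responses, positive values late ones.
#'
#' @param response_time_ms Button-press time(s), ms from motion onset.
#' @param contact_time_ms Correct contact time(s), ms from motion onset.
#' @return Signed constant error in ms (vectorised).
#' @export
ttc_constant_error <- function(response_time_ms, contact_time_ms) {
  response_time_ms - contact_time_ms
}

#' Variable error of a cell of constant errors
#'
#' Sample SD of the constant errors; the response-variability measure that
#' is independent of accuracy (invariant to constant bias).
#'
#' @param constant_errors_ms Constant errors of one cell (ms).
#' @return Sample SD in ms, NA if fewer than 2 finite values.
#' @export
ttc_variable_error <- function(constant_errors_ms) {
  x <- constant_errors_ms[is.finite(constant_errors_ms)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}

#' Reaction time from occlusion onset
#'
#' `response_time - occlusion_onset`. Responses at or before occlusion onset
#' are anticipatory and flagged.
#'
#' @param response_time_ms Button-press time(s), ms from motion onset.
#' @param occlusion_onset_ms Occlusion onset (ms, = presentation duration).
#' @return data.frame with `reaction_time_ms` and `anticipatory` flag.
#' @export
ttc_reaction_time <- function(response_time_ms, occlusion_onset_ms) {
  rt <- response_time_ms - occlusion_onset_ms
  data.frame(reaction_time_ms = rt, anticipatory = rt <= 0)
}

#' Trial-level TTC errors for a dataset
#'
#' Adds constant error, absolute error and reaction time columns to a
#' trials table carrying `response_ms`, `velocity` (and optionally
#' `visual_condition`, `observer_id`).
#'
#' @param trials data.frame with at least `response_ms` and `velocity`.
#' @param geometry A [stimulus_geometry()].
#' @return The input with `contact_ms`, `constant_error_ms`,
#'   `absolute_error_ms`, `reaction_time_ms`, `anticipatory` appended;
#'   trials with missing responses are dropped with a warning.
#' @export
ttc_trial_errors <- function(trials, geometry = stimulus_geometry()) {
  miss <- !is.finite(trials$response_ms)
  if (any(miss)) {
    warning(sum(miss), " trial(s) without a response dropped")
    trials <- trials[!miss, , drop = FALSE]
  }
  trials$contact_ms <- contact_time(geometry, trials$velocity)
  trials$constant_error_ms <- ttc_constant_error(trials$response_ms,
                                                 trials$contact_ms)
  trials$absolute_error_ms <- abs(trials$constant_error_ms)
  rt <- ttc_reaction_time(trials$response_ms,
                          geometry$presentation_duration)
  trials$reaction_time_ms <- rt$reaction_time_ms
  trials$anticipatory <- rt$anticipatory
  trials
}

#' Aggregate TTC errors per cell
#'
#' Per (observer, condition, velocity) cell: mean constant error, mean
#' absolute error, variable error (SD of constant error) and mean reaction
#' time. A pooled-over-velocity variable error per (observer, condition) is
#' returned alongside, since "per visual condition" is ambiguous between
#' the two readings.
#'
#' @param trial_errors Output of [ttc_trial_errors()], QC-passing trials.
#' @return List with `cells` (per observer x condition x velocity) and
#'   `pooled` (variable error per observer x condition).
#' @export
ttc_aggregate <- function(trial_errors) {
  stopifnot(all(c("observer_id", "visual_condition", "velocity",
                  "constant_error_ms") %in% names(trial_errors)))
  key <- interaction(trial_errors$observer_id, trial_errors$visual_condition,
                     trial_errors$velocity, drop = TRUE)
  cells <- do.call(rbind, lapply(split(trial_errors, key), function(d) {
    data.frame(observer_id = d$observer_id[1],
               visual_condition = d$visual_condition[1],
               velocity = d$velocity[1],
               mean_constant_error_ms = mean(d$constant_error_ms),
               mean_absolute_error_ms = mean(d$absolute_error_ms),
               variable_error_ms = ttc_variable_error(d$constant_error_ms),
               mean_reaction_time_ms = mean(d$reaction_time_ms),
               n = nrow(d))
  }))
  rownames(cells) <- NULL
  key2 <- interaction(trial_errors$observer_id,
                      trial_errors$visual_condition, drop = TRUE)
  pooled <- do.call(rbind, lapply(split(trial_errors, key2), function(d) {
    data.frame(observer_id = d$observer_id[1],
               visual_condition = d$visual_condition[1],
               variable_error_pooled_ms =
                 ttc_variable_error(d$constant_error_ms),
               n = nrow(d))
  }))
  rownames(pooled) <- NULL
  list(cells = cells, pooled = pooled)
}

#' Previous-trial (n-1) subdivision of constant errors
#'
#' Keys every trial's constant error by (current velocity, previous trial's
#' velocity) within each visual condition, for the sequential-bias analysis.
#' The first trial of each block has no valid predecessor and is excluded.
#' Predecessors that failed QC still contribute their *presented* velocity
#' (the stimulus was seen even if the trial's data were discarded), so the
#' keying is done on the full session order before any QC filtering of the
#' predecessor.
#'
#' @param trial_errors Trial table with `observer_id`, `block`, `trial_id`,
#'   `visual_condition`, `velocity`, `constant_error_ms`; `trial_id` carries
#'   the session presentation order. If a `qc_keep` column is present, only
#'   QC-passing *current* trials enter the table.
#' @return data.frame: observer_id, visual_condition, velocity,
#'   prev_velocity, constant_error_ms (one row per usable trial), plus a
#'   `cell_means` attribute with per (observer, condition, v, v_prev) means.
#' @export
previous_trial_table <- function(trial_errors) {
  stopifnot(all(c("observer_id", "block", "trial_id", "velocity",
                  "constant_error_ms") %in% names(trial_errors)))
  out <- do.call(rbind, lapply(split(trial_errors, trial_errors$observer_id),
                               function(d) {
    d <- d[order(d$trial_id), , drop = FALSE]
    prev_v <- c(NA, d$velocity[-nrow(d)])
    prev_block <- c(NA, d$block[-nrow(d)])
    prev_id <- c(NA, d$trial_id[-nrow(d)])
    ok <- !is.na(prev_v) & prev_block == d$block & prev_id == d$trial_id - 1
    d <- d[ok, , drop = FALSE]
    d$prev_velocity <- prev_v[ok]
    d
  }))
  if (!is.null(out$qc_keep)) out <- out[out$qc_keep, , drop = FALSE]
  rownames(out) <- NULL
  key <- interaction(out$observer_id, out$visual_condition, out$velocity,
                     out$prev_velocity, drop = TRUE)
  cm <- do.call(rbind, lapply(split(out, key), function(d) {
    data.frame(observer_id = d$observer_id[1],
               visual_condition = d$visual_condition[1],
               velocity = d$velocity[1],
               prev_velocity = d$prev_velocity[1],
               mean_constant_error_ms = mean(d$constant_error_ms),
               n = nrow(d))
  }))
  rownames(cm) <- NULL
  attr(out, "cell_means") <- cm
  out
}
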