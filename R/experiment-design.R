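#' Visual conditions of the paradigm
#'
#' The three visual conditions crossed with object velocity in the factorial
#' design: eye fixation on the stationary object while the other object moves,
#' and smooth pursuit of a first-order (luminance-defined) or second-order
#' (contrast-defined) moving object.
#'
#' @return Character vector of the three condition labels.
#' @export
visual_conditions <- function() {
  c("fixation", "pursuit_first_order", "pursuit_second_order")
}

#' Stimulus geometry of the time-to-contact display
#'
#' Two random-dot objects, each windowed by a Gaussian contrast envelope, are
#' placed symmetrically about screen centre. One object moves toward the
#' other at constant velocity; both disappear at occlusion onset and the
#' observer estimates when the moving object would have reached the
#' stationary one.
#'
#' @param separation Distance between the two objects in deg (default 6).
#' @param eccentricity Eccentricity of each object from screen centre in deg
#'   (default 3; objects at -eccentricity and +eccentricity).
#' @param window_sd SD of the Gaussian contrast window in deg (default 0.4).
#' @param dot_density Fraction of texture pixels carrying a dot (default 0.5).
#' @param presentation_duration Visible motion duration in ms (default 500).
#' @param velocities Object velocities (deg/s) the geometry must support.
#'
#' @return An object of class `stimulus_geometry`.
#' @details The presentation must end before the objects touch for every
#'   supported velocity (`presentation_duration < separation / velocity`),
#'   otherwise there is nothing to extrapolate; this is enforced.
#' @export
stimulus_geometry <- function(separation = 6, eccentricity = 3,
                              window_sd = 0.4, dot_density = 0.5,
                              presentation_duration = 500,
                              velocities = c(3, 4, 5)) {
  stopifnot(separation > 0, eccentricity > 0, window_sd > 0,
            dot_density > 0, dot_density <= 1,
            presentation_duration > 0, all(velocities > 0))
  if (any(presentation_duration >= 1000 * separation / velocities)) {
    stop("presentation_duration must be shorter than separation/velocity ",
         "for every supported velocity (objects must vanish before contact)")
  }
  structure(
    list(separation = separation, eccentricity = eccentricity,
         window_sd = window_sd, dot_density = dot_density,
         presentation_duration = presentation_duration,
         velocities = velocities),
    class = "stimulus_geometry")
}

#' Trial timeline constants
#'
#' @param cue_duration Condition-cue display duration in ms (default 2500).
#' @param pretrial_range Range (ms) of the uniformly jittered fixation period
#'   before motion onset (default c(1000, 1500)).
#' @param presentation_duration Visible motion duration in ms; occlusion
#'   onset equals this value on the motion-onset clock.
#' @param intertrial_interval Trial start-to-start interval in ms.
#'
#' @return An object of class `trial_timeline`. Time 0 is motion onset.
#' @export
trial_timeline <- function(cue_duration = 2500,
                           pretrial_range = c(1000, 1500),
                           presentation_duration = 500,
                           intertrial_interval = 5000) {
  stopifnot(length(pretrial_range) == 2, pretrial_range[1] <= pretrial_range[2],
            pretrial_range[1] > 0, presentation_duration > 0)
  structure(
    list(cue_duration = cue_duration, pretrial_range = pretrial_range,
         motion_onset = 0,
         occlusion_onset = presentation_duration,
         intertrial_interval = intertrial_interval),
    class = "trial_timeline")
}

#' Trial condition descriptor
#'
#' In the fixation condition the left object is stationary (and gazed) while
#' the right object moves leftward; in both pursuit conditions the left
#' object moves rightward and is tracked. Motion direction is therefore
#' derived from the condition, rightward positive.
#'
#' @param visual_condition One of [visual_conditions()].
#' @param velocity Object speed in deg/s.
#' @return A `trial_condition` list with `motion_direction` (+1 rightward,
#'   -1 leftward), `moving_object` ("left"/"right") and `gazed_object`.
#' @export
trial_condition <- function(visual_condition, velocity) {
  visual_condition <- match.arg(visual_condition, visual_conditions())
  stopifnot(is.numeric(velocity), length(velocity) == 1, velocity > 0)
  fixation <- visual_condition == "fixation"
  structure(
    list(visual_condition = visual_condition,
         velocity = velocity,
         motion_direction = if (fixation) -1 else +1,
         moving_object = if (fixation) "right" else "left",
         gazed_object = "left"),
    class = "trial_condition")
}

#' Time of contact of the moving object with the stationary object
#'
#' The correct response time of the task: with constant velocity, the moving
#' object covers `separation` deg in `separation / velocity` seconds, so the
#' contact time on the motion-onset clock is `1000 * separation / velocity`
#' ms. With the default 6-deg separation this is 2000, 1500, and 1200 ms for
#' 3, 4 and 5 deg/s.
#'
#' @param geometry A [stimulus_geometry()].
#' @param velocity Object speed in deg/s (> 0); vectorised.
#' @return Contact time(s) in ms from motion onset.
#' @export
contact_time <- function(geometry, velocity) {
  stopifnot(inherits(geometry, "stimulus_geometry"))
  if (any(!is.finite(velocity)) || any(velocity <= 0)) {
    stop("velocity must be positive and finite")
  }
  1000 * geometry$separation / velocity
}

#' Step-ramp (Rashbass) target trajectory
#'
#' The target steps *backwards* (opposite to its motion direction) by
#' `velocity * step_recross_s` deg at motion onset and then ramps forward at
#' constant velocity, recrossing its initial position exactly
#' `step_recross_s` seconds later (100 ms by default). The backward step
#' suppresses the initial catch-up saccade.
#'
#' @param velocity Target speed in deg/s (> 0).
#' @param duration Trajectory duration in ms.
#' @param dt Sample interval in ms; must divide `duration`.
#' @param step_recross_ms Time (ms) at which the ramp recrosses the initial
#'   position; the step size is `velocity * step_recross_ms / 1000` deg.
#' @return A data.frame with `t_ms` (0 .. duration) and `position_deg`
#'   relative to the target's initial (pre-step) position, positive along the
#'   motion direction.
#' @export
step_ramp_trajectory <- function(velocity, duration, dt = 1,
                                 step_recross_ms = 100) {
  stopifnot(velocity > 0, duration > 0, dt > 0)
  if (abs(duration / dt - round(duration / dt)) > 1e-9) {
    stop("dt must divide duration")
  }
  t_ms <- seq(0, duration, by = dt)
  step <- velocity * step_recross_ms / 1000 # deg
  position <- velocity * t_ms / 1000 - step
  data.frame(t_ms = t_ms, position_deg = position)
}

#' Window-centre and texture-phase descriptor of the motion stimulus
#'
#' First-order motion: the Gaussian window and the dot texture translate
#' together (texture phase displacement equals window displacement).
#' Second-order motion: only the contrast window moves over a static texture
#' (texture phase stays 0). The fixation condition's right, leftward-moving
#' object is a first-order stimulus. Displacements follow the step-ramp
#' trajectory, signed by the condition's motion direction.
#'
#' @param condition A [trial_condition()].
#' @param t_ms Time(s) within the presentation, in ms from motion onset.
#' @param geometry A [stimulus_geometry()] (for the presentation bounds).
#' @param step_recross_ms Step-ramp recross time in ms.
#' @return data.frame with `t_ms`, `window_center_deg`, `texture_phase_deg`,
#'   both relative to the moving object's initial screen position.
#' @export
motion_descriptor <- function(condition, t_ms,
                              geometry = stimulus_geometry(),
                              step_recross_ms = 100) {
  stopifnot(inherits(condition, "trial_condition"))
  if (any(t_ms < 0 | t_ms > geometry$presentation_duration)) {
    stop("t_ms outside the presentation period")
  }
  step <- condition$velocity * step_recross_ms / 1000
  disp <- (condition$velocity * t_ms / 1000 - step) * condition$motion_direction
  second_order <- condition$visual_condition == "pursuit_second_order"
  data.frame(
    t_ms = t_ms,
    window_center_deg = disp,
    texture_phase_deg = if (second_order) 0 * disp else disp)
}

#' Build a randomly interleaved factorial session
#'
#' Crosses the visual conditions with the object velocities, repeats every
#' cell `n_per_cell` times, shuffles the whole list with a seeded RNG, and
#' assigns trials to `n_blocks` equal blocks in presentation order. Each
#' trial draws its own pretrial fixation duration uniformly from
#' `timeline$pretrial_range`.
#'
#' @param n_per_cell Trials per (condition, velocity) cell (default 20).
#' @param n_blocks Number of blocks (default 5).
#' @param conditions Character vector of visual conditions.
#' @param velocities Numeric vector of object velocities (deg/s).
#' @param timeline A [trial_timeline()].
#' @param seed Integer RNG seed; the same seed reproduces the same session.
#' @return A `session_design`: data.frame with columns `trial_id`, `block`,
#'   `visual_condition`, `velocity`, `pretrial_ms`, plus attributes `seed`,
#'   `n_per_cell`, `n_blocks`.
#' @export
build_session <- function(n_per_cell = 20, n_blocks = 5,
                          conditions = visual_conditions(),
                          velocities = c(3, 4, 5),
                          timeline = trial_timeline(),
                          seed = 1L) {
  stopifnot(n_per_cell >= 1, n_blocks >= 1,
            length(conditions) >= 1, length(velocities) >= 1)
  cells <- expand.grid(visual_condition = conditions, velocity = velocities,
                       stringsAsFactors = FALSE)
  n_trials <- nrow(cells) * n_per_cell
  if (n_trials %% n_blocks != 0) {
    stop("n_per_cell * number of cells must be divisible by n_blocks")
  }
  trials <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  pre <- timeline$pretrial_range
  drawn <- with_seed(seed, {
    list(ord = sample.int(n_trials),
         pretrial = stats::runif(n_trials, pre[1], pre[2]))
  })
  trials <- trials[drawn$ord, , drop = FALSE]
  trials$trial_id <- seq_len(n_trials)
  trials$block <- rep(seq_len(n_blocks), each = n_trials / n_blocks)
  trials$pretrial_ms <- drawn$pretrial
  rownames(trials) <- NULL
  out <- trials[, c("trial_id", "block", "visual_condition", "velocity",
                    "pretrial_ms")]
  attr(out, "seed") <- seed
  attr(out, "n_per_cell") <- n_per_cell
  attr(out, "n_blocks") <- n_blocks
  attr(out, "timeline") <- timeline
  class(out) <- c("session_design", "data.frame")
  out
}
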