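#' Curriculum stage
#'
#' One rung of the shaping ladder: a task, how many sessions it runs, the
#' dot diameter, and the fraction of forced-choice trials (only the
#' sequencing task may have a non-zero forced fraction).
#'
#' @param task One of `"one_dot"`, `"two_dot"`, `"two_number_dot"`.
#' @param n_sessions Number of sessions in the stage (>= 1).
#' @param dot_diameter_px Dot diameter in pixels (default 100; the One Dot
#'   stages shrink it from 550 down to 100).
#' @param forced_fraction Proportion of forced-choice trials in `[0, 1]`.
#' @return Object of class `dot_stage`.
#' @export
curriculum_stage <- function(task, n_sessions, dot_diameter_px = 100,
                             forced_fraction = 0) {
  if (!task %in% TASKS)
    dt_spec_error(sprintf("unknown task '%s'", task))
  n_sessions <- check_count(n_sessions, "n_sessions", min = 1L)
  check_number(dot_diameter_px, "dot_diameter_px", min = 0, strict_min = TRUE)
  check_number(forced_fraction, "forced_fraction", min = 0, max = 1)
  if (forced_fraction > 0 && task != "two_number_dot")
    dt_spec_error("forced_fraction > 0 is only meaningful for two_number_dot")
  structure(list(task = task, n_sessions = n_sessions,
                 dot_diameter_px = dot_diameter_px,
                 forced_fraction = forced_fraction),
            class = "dot_stage")
}

new_curriculum <- function(stages) {
  structure(list(stages = stages), class = "dot_curriculum")
}

#' The 95-session training curriculum
#'
#' Builds the step-by-step shaping schedule used to train touchscreen-naive
#' groups: ten One Dot sessions with the dot shrinking from 550 to 100 px
#' (3 sessions at 550, 2 at 400, 2 at 200, 3 at 100), five Two Dot sessions,
#' then eighty Two Number Dot sessions of which the final 55 interleave
#' forced-choice trials at 25%.
#'
#' @return Object of class `dot_curriculum` (ordered list of
#'   [curriculum_stage()]s, 95 sessions in total).
#' @examples
#' cur <- build_training_curriculum()
#' total_sessions(cur)
#' @export
build_training_curriculum <- function() {
  new_curriculum(list(
    curriculum_stage("one_dot", 3, dot_diameter_px = 550),
    curriculum_stage("one_dot", 2, dot_diameter_px = 400),
    curriculum_stage("one_dot", 2, dot_diameter_px = 200),
    curriculum_stage("one_dot", 3, dot_diameter_px = 100),
    curriculum_stage("two_dot", 5),
    curriculum_stage("two_number_dot", 25, forced_fraction = 0),
    curriculum_stage("two_number_dot", 55, forced_fraction = 0.25)
  ))
}

#' Total number of sessions in a curriculum
#' @param curriculum A `dot_curriculum`.
#' @return Integer session count.
#' @export
total_sessions <- function(curriculum) {
  sum(vapply(curriculum$stages, function(s) s$n_sessions, integer(1)))
}

#' Stage containing a given session
#'
#' Maps a 1-based session index to its stage under cumulative ordering.
#'
#' @param curriculum A `dot_curriculum`.
#' @param session_index Session index in `1..total_sessions(curriculum)`.
#' @return The [curriculum_stage()] covering that session.
#' @export
stage_for_session <- function(curriculum, session_index) {
  session_index <- check_count(session_index, "session_index", min = 1L)
  total <- total_sessions(curriculum)
  if (session_index > total)
    dt_spec_error(sprintf("session_index %d out of range 1..%d",
                          session_index, total))
  cum <- 0L
  for (st in curriculum$stages) {
    cum <- cum + st$n_sessions
    if (session_index <= cum) return(st)
  }
}

#' Generate a trial sequence for a stage
#'
#' Produces `n_trials` fully specified trials with freshly placed stimuli.
#' Forced-choice flags are balanced in windows: each consecutive window of
#' `round(1 / forced_fraction)` trials contains exactly one forced trial at
#' a uniformly random position, so the nominal forced percentage is exact
#' whenever `n_trials` is a multiple of the window. Trials in a trailing
#' partial window are forced independently with probability
#' `forced_fraction`.
#'
#' @param stage A [curriculum_stage()].
#' @param n_trials Number of trials (>= 0).
#' @param screen A [screen_spec()] used for stimulus placement.
#' @param min_gap_px Extra clearance passed to [sample_dot_placement()].
#' @return List of [trial_spec()] objects.
#' @export
generate_trial_sequence <- function(stage, n_trials, screen = screen_spec(),
                                    min_gap_px = 0) {
  n_trials <- check_count(n_trials, "n_trials", min = 0L)
  if (n_trials == 0L) return(list())
  forced <- forced_flags(stage$forced_fraction, n_trials)
  lapply(seq_len(n_trials), function(k) {
    f <- stage$task == "two_number_dot" && forced[k]
    trial_spec(stage$task, k,
               build_trial_stimuli(stage, f, screen, min_gap_px),
               forced = f, dot_diameter_px = stage$dot_diameter_px)
  })
}

# windowed forced-flag assignment (exact count over full windows,
# Bernoulli on the trailing remainder)
forced_flags <- function(forced_fraction, n_trials) {
  if (forced_fraction <= 0) return(rep(FALSE, n_trials))
  window <- round(1 / forced_fraction)
  if (abs(window - 1 / forced_fraction) > 1e-9)
    dt_config_error("forced_fraction must be the reciprocal of an integer window size")
  flags <- rep(FALSE, n_trials)
  n_full <- n_trials %/% window
  if (n_full > 0) {
    pos <- sample.int(window, n_full, replace = TRUE)
    flags[(seq_len(n_full) - 1L) * window + pos] <- TRUE
  }
  rem <- n_trials %% window
  if (rem > 0) {
    idx <- n_full * window + seq_len(rem)
    flags[idx] <- stats::runif(rem) < forced_fraction
  }
  flags
}

#' @export
print.dot_curriculum <- function(x, ...) {
  cat("<dot_curriculum>", total_sessions(x), "sessions\n")
  cum <- 0L
  for (st in x$stages) {
    cat(sprintf("  sessions %2d-%2d  %-15s dot %3g px  forced %g%%\n",
                cum + 1L, cum + st$n_sessions, st$task,
                st$dot_diameter_px, 100 * st$forced_fraction))
    cum <- cum + st$n_sessions
  }
  invisible(x)
}

#' Session specs for a curriculum slice
#'
#' Convenience builder: one [session_spec()] per session index, with
#' per-session seeds derived deterministically from `base_seed`.
#'
#' @param curriculum A `dot_curriculum`.
#' @param sessions Integer vector of session indices (default all).
#' @param base_seed Integer; session `i` gets seed `base_seed + i`.
#' @param group_id Group label recorded in the logs.
#' @param ... Passed to [session_spec()] (e.g. `duration_s`, `iti_s`).
#' @return List of `dot_session_spec`.
#' @export
curriculum_session_specs <- function(curriculum,
                                     sessions = seq_len(total_sessions(curriculum)),
                                     base_seed = 1L, group_id = "sim", ...) {
  lapply(sessions, function(i)
    session_spec(i, stage_for_session(curriculum, i),
                 seed = base_seed + i, group_id = group_id, ...))
}
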