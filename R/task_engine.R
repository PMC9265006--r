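# Session clock granularity: every touch and every trial consumes at least
# one tick, which keeps degenerate zero-latency / zero-ITI configurations
# finite (trial throughput is then bounded by duration / tick).
CLOCK_TICK_S <- 0.001

TASKS <- c("one_dot", "two_dot", "two_number_dot")

#' Trial specification
#'
#' What a single trial presents. Stimulus composition is checked against the
#' task: One Dot shows one unlabeled dot; Two Dot shows two unlabeled dots;
#' Two Number Dot choice trials show dots labeled "1" and "2"; forced-choice
#' trials show only the "1" dot (no error is possible).
#'
#' @param task One of `"one_dot"`, `"two_dot"`, `"two_number_dot"`.
#' @param trial_index 1-based trial index within the session.
#' @param stimuli List of [dot_stimulus()] objects.
#' @param forced Logical; only meaningful for `two_number_dot`.
#' @param dot_diameter_px The curriculum's dot size for this trial.
#' @return Object of class `dot_trial_spec`.
#' @export
trial_spec <- function(task, trial_index, stimuli, forced = FALSE,
                       dot_diameter_px = 100) {
  if (!task %in% TASKS)
    dt_spec_error(sprintf("unknown task '%s'", task))
  trial_index <- check_count(trial_index, "trial_index", min = 1L)
  labels <- vapply(stimuli, function(s) s$label, character(1))
  bad <- switch(task,
    one_dot = length(stimuli) != 1L || any(labels != "none"),
    two_dot = length(stimuli) != 2L || any(labels != "none"),
    two_number_dot = if (isTRUE(forced))
      length(stimuli) != 1L || labels[1] != "1"
    else
      length(stimuli) != 2L || !setequal(labels, c("1", "2"))
  )
  if (bad)
    dt_spec_error(sprintf("stimuli do not match task '%s' (forced=%s)",
                          task, isTRUE(forced)))
  structure(list(task = task, trial_index = trial_index, stimuli = stimuli,
                 forced = isTRUE(forced) && task == "two_number_dot",
                 dot_diameter_px = dot_diameter_px),
            class = "dot_trial_spec")
}

feedback_event <- function(kind, time_s) {
  list(kind = kind, time_s = time_s)
}

#' Run one trial
#'
#' Drives the per-task state machine. The agent is repeatedly asked for its
#' next touch given the currently visible stimuli; touches that miss every
#' visible dot are logged but change nothing. Outcomes:
#' * `one_dot`: first hit on the dot is correct.
#' * `two_dot`: each hit hides its dot; correct once both are hidden
#'   (either order).
#' * `two_number_dot` (choice): hitting "1" hides it; subsequently hitting
#'   "2" is correct. Hitting "2" while "1" is still visible ends the trial
#'   immediately as incorrect.
#' * forced trial: a hit on the lone "1" dot is correct.
#'
#' Correct trials emit `chime`, `led_green`, `pellet`; incorrect trials emit
#' `buzzer`, `led_red`. A trial not resolved within `max_trial_duration_s`
#' ends as `aborted` with no feedback.
#'
#' @param spec A [trial_spec()].
#' @param agent An agent (see [ideal_agent()] for the interface).
#' @param screen A [screen_spec()].
#' @param onset_s Trial onset on the session clock.
#' @param max_trial_duration_s Seconds before an unresolved trial is aborted.
#' @return List with elements `result` (class `dot_trial_result`) and
#'   `events` (list of feedback events stamped at trial end).
#' @export
run_trial <- function(spec, agent, screen = screen_spec(), onset_s = 0,
                      max_trial_duration_s = 60) {
  if (!inherits(spec, "dot_trial_spec"))
    dt_spec_error("`spec` must be a dot_trial_spec")
  stimuli <- spec$stimuli
  visible <- rep(TRUE, length(stimuli))
  cutoff <- onset_s + max_trial_duration_s
  now <- onset_s
  touches <- list()
  outcome <- NULL
  end_s <- NA_real_

  repeat {
    vis <- stimuli[visible]
    tk <- agent$next_touch(vis, screen, now)
    if (is.null(tk)) { outcome <- "aborted"; end_s <- cutoff; break }
    t_touch <- max(now + tk$latency_s, now + CLOCK_TICK_S)
    if (t_touch > cutoff) { outcome <- "aborted"; end_s <- cutoff; break }
    now <- t_touch
    hit_id <- NA_character_
    for (i in seq_along(stimuli)) {
      if (!visible[i]) next
      if (hit_test(stimuli[[i]],
                   list(x_px = tk$x_px, y_px = tk$y_px))) {
        hit_id <- stimuli[[i]]$dot_id
        hit_i <- i
        break
      }
    }
    touches[[length(touches) + 1L]] <-
      list(time_s = now, x_px = tk$x_px, y_px = tk$y_px, hit = hit_id)
    if (is.na(hit_id)) next  # background touch: logged, no state change

    lab <- stimuli[[hit_i]]$label
    if (spec$task == "one_dot") {
      visible[hit_i] <- FALSE
      outcome <- "correct"; end_s <- now; break
    } else if (spec$task == "two_dot") {
      visible[hit_i] <- FALSE
      if (!any(visible)) { outcome <- "correct"; end_s <- now; break }
    } else {  # two_number_dot
      if (spec$forced) {
        visible[hit_i] <- FALSE
        outcome <- "correct"; end_s <- now; break
      }
      if (lab == "1") {
        visible[hit_i] <- FALSE
      } else if (any(visible & vapply(stimuli, function(s) s$label, character(1)) == "1")) {
        outcome <- "incorrect"; end_s <- now; break
      } else {
        visible[hit_i] <- FALSE
        outcome <- "correct"; end_s <- now; break
      }
    }
  }

  rewarded <- identical(outcome, "correct")
  events <- if (rewarded) {
    list(feedback_event("chime", end_s),
         feedback_event("led_green", end_s),
         feedback_event("pellet", end_s))
  } else if (identical(outcome, "incorrect")) {
    list(feedback_event("buzzer", end_s),
         feedback_event("led_red", end_s))
  } else list()

  latency <- if (length(touches)) touches[[1L]]$time_s - onset_s else NA_real_
  result <- structure(list(
    trial_index = spec$trial_index, task = spec$task, forced = spec$forced,
    outcome = outcome, rewarded = rewarded, touches = touches,
    response_latency_s = latency, onset_s = onset_s, end_s = end_s,
    stimuli = stimuli), class = "dot_trial_result")

  if (is.function(agent$notify_trial_outcome)) agent$notify_trial_outcome(result)
  list(result = result, events = events)
}

#' Session specification
#'
#' Timing and provenance for one session. Defaults follow the training
#' protocol: 10-minute sessions, a 3-second inter-trial interval, and a
#' 60-second response timeout for simulation.
#'
#' @param session_index 1-based session index within the curriculum.
#' @param stage A [curriculum_stage()] defining task and parameters.
#' @param duration_s Session length in seconds (default 600).
#' @param iti_s Inter-trial interval in seconds (default 3).
#' @param max_trial_duration_s Response timeout per trial (default 60).
#' @param seed Integer seed; the session is fully reproducible given the
#'   seed and a deterministic agent.
#' @param group_id Free-text identifier of the (simulated) subject group.
#' @return Object of class `dot_session_spec`.
#' @export
session_spec <- function(session_index, stage, duration_s = 600,
                         iti_s = 3, max_trial_duration_s = 60,
                         seed = 1L, group_id = "sim") {
  session_index <- check_count(session_index, "session_index", min = 1L)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(iti_s, "iti_s", min = 0)
  check_number(max_trial_duration_s, "max_trial_duration_s", min = 0,
               strict_min = TRUE)
  structure(list(session_index = session_index, stage = stage,
                 duration_s = duration_s, iti_s = iti_s,
                 max_trial_duration_s = max_trial_duration_s,
                 seed = as.integer(seed), group_id = group_id),
            class = "dot_session_spec")
}

# lazily draws one forced position per window of `window` trials
forced_scheduler <- function(forced_fraction, window = 4L) {
  if (forced_fraction <= 0) return(function() FALSE)
  pos_in_window <- 0L
  forced_pos <- NA_integer_
  function() {
    pos_in_window <<- pos_in_window + 1L
    if (pos_in_window > window) pos_in_window <<- 1L
    if (pos_in_window == 1L) forced_pos <<- sample.int(window, 1L)
    pos_in_window == forced_pos
  }
}

build_trial_stimuli <- function(stage, forced, screen, min_gap_px = 0) {
  d <- stage$dot_diameter_px
  switch(stage$task,
    one_dot = sample_dot_placement(screen, d, min_gap_px),
    two_dot = sample_dot_placement(screen, c(d, d), min_gap_px),
    two_number_dot = if (forced)
      sample_dot_placement(screen, d, min_gap_px, labels = "1")
    else
      sample_dot_placement(screen, c(d, d), min_gap_px, labels = c("1", "2"))
  )
}

#' Run one timed session
#'
#' Emits a `session_start_chime` at t = 0 and then runs trials back to back:
#' each trial's stimuli are freshly placed at random, trials are separated by
#' the inter-trial interval, no new trial starts at or after `duration_s`,
#' and a trial in flight at the cutoff is allowed to complete. The session
#' seeds the global RNG once at the start, so the full log is reproducible
#' given the seed and a deterministic agent.
#'
#' @param spec A [session_spec()].
#' @param agent An agent (see [ideal_agent()]).
#' @param screen A [screen_spec()].
#' @param min_gap_px Extra clearance passed to [sample_dot_placement()].
#' @return Object of class `dot_session_log` with elements `spec`, `trials`,
#'   `events`, and `metadata`.
#' @examples
#' stage <- curriculum_stage("one_dot", 1, dot_diameter_px = 100)
#' log <- run_session(session_spec(1, stage, seed = 7), ideal_agent())
#' trials_per_minute(log)
#' @export
run_session <- function(spec, agent, screen = screen_spec(), min_gap_px = 0) {
  if (!inherits(spec, "dot_session_spec"))
    dt_spec_error("`spec` must be a dot_session_spec")
  set.seed(spec$seed)
  if (is.function(agent$reset)) agent$reset()
  stage <- spec$stage
  next_forced <- forced_scheduler(stage$forced_fraction)
  events <- list(feedback_event("session_start_chime", 0))
  trials <- list()
  t <- 0
  k <- 0L
  while (t < spec$duration_s) {
    k <- k + 1L
    forced <- stage$task == "two_number_dot" && next_forced()
    stimuli <- build_trial_stimuli(stage, forced, screen, min_gap_px)
    tsp <- trial_spec(stage$task, k, stimuli, forced = forced,
                      dot_diameter_px = stage$dot_diameter_px)
    out <- run_trial(tsp, agent, screen, onset_s = t,
                     max_trial_duration_s = spec$max_trial_duration_s)
    trials[[k]] <- out$result
    events <- c(events, out$events)
    t <- max(out$result$end_s + spec$iti_s, t + CLOCK_TICK_S)
  }
  structure(list(spec = spec, trials = trials, events = events,
                 metadata = list(group_id = spec$group_id,
                                 session_index = spec$session_index,
                                 task = stage$task,
                                 date = NA_character_)),
            class = "dot_session_log")
}

#' Run a queue of sessions
#'
#' Sessions run in order with independent session clocks. An error inside
#' one session is captured (the condition object takes the log's slot) and
#' does not stop the remaining sessions.
#'
#' @param specs List of [session_spec()] objects.
#' @param agent An agent, shared across sessions (learning agents carry
#'   their state forward).
#' @param screen A [screen_spec()].
#' @return List of `dot_session_log` objects (or conditions), in order.
#' @export
run_session_queue <- function(specs, agent, screen = screen_spec()) {
  lapply(specs, function(sp)
    tryCatch(run_session(sp, agent, screen), error = function(e) e))
}

#' @export
print.dot_session_log <- function(x, ...) {
  n <- length(x$trials)
  nc <- sum(vapply(x$trials, function(tr) tr$outcome == "correct", logical(1)))
  cat(sprintf("<dot_session_log> session %d | task %s | %d trials (%d correct) | %g s\n",
              x$spec$session_index, x$metadata$task, n, nc, x$spec$duration_s))
  invisible(x)
}
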