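# Generators for valid (and deliberately corrupted) log content used by the
# round-trip and validation tests. All randomness flows from the caller's
# seed via the global RNG.

random_trial_records <- function(n_trials = NULL, session_index = 1L,
                                 group_id = "fuzz") {
  if (is.null(n_trials)) n_trials <- sample(1:40, 1)
  task <- sample(c("one_dot", "two_dot", "two_number_dot"), 1)
  onset <- round(cumsum(runif(n_trials, 0.5, 8)), 3)
  dur <- round(runif(n_trials, 0.001, 5), 3)
  forced <- if (task == "two_number_dot") rbinom(n_trials, 1, 0.25) else rep(0L, n_trials)
  outcome <- ifelse(forced == 1L, "correct",
                    sample(c("correct", "incorrect", "aborted"), n_trials,
                           replace = TRUE, prob = c(0.6, 0.25, 0.15)))
  outcome[task != "two_number_dot" & outcome == "incorrect"] <- "correct"
  touched <- outcome != "aborted" | rbinom(n_trials, 1, 0.3) == 1L
  two_dots <- task %in% c("two_dot", "two_number_dot") & !(forced == 1L)
  data.frame(
    group_id = group_id,
    session_index = as.integer(session_index),
    task = task,
    trial_index = seq_len(n_trials),
    forced = as.integer(forced),
    outcome = outcome,
    rewarded = as.integer(outcome == "correct"),
    onset_s = onset,
    end_s = round(onset + dur, 3),
    response_latency_s = ifelse(touched, round(runif(n_trials, 0.05, 3), 3), NA_real_),
    n_touches = ifelse(touched, sample(1:5, n_trials, replace = TRUE), 0L),
    dot1_x = round(runif(n_trials, 50, 974)),
    dot1_y = round(runif(n_trials, 50, 718)),
    dot1_diam = 100,
    dot1_label = if (task == "two_number_dot") "1" else "none",
    dot2_x = ifelse(two_dots, round(runif(n_trials, 50, 974)), NA_real_),
    dot2_y = ifelse(two_dots, round(runif(n_trials, 50, 718)), NA_real_),
    dot2_diam = ifelse(two_dots, 100, NA_real_),
    dot2_label = ifelse(two_dots, if (task == "two_number_dot") "2" else "none",
                        NA_character_),
    first_touch_x = ifelse(touched, round(runif(n_trials, 0, 1023), 3), NA_real_),
    first_touch_y = ifelse(touched, round(runif(n_trials, 0, 767), 3), NA_real_),
    stringsAsFactors = FALSE
  )
}

random_event_table <- function(n = NULL, session_index = 1L) {
  if (is.null(n)) n <- sample(1:60, 1)
  data.frame(
    kind = c("session_start_chime",
             sample(c("chime", "buzzer", "led_green", "led_red", "pellet"),
                    n - 1, replace = TRUE)),
    time_s = round(sort(runif(n, 0, 600)), 3),
    session_index = as.integer(session_index))
}
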