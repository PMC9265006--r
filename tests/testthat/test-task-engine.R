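test_that("trial_spec enforces task/stimulus composition", {
  scr <- screen_spec()
  one <- sample_dot_placement(scr, 100)
  two <- sample_dot_placement(scr, c(100, 100))
  lab <- sample_dot_placement(scr, c(100, 100), labels = c("1", "2"))
  expect_s3_class(trial_spec("one_dot", 1, one), "dot_trial_spec")
  expect_error(trial_spec("one_dot", 1, two), class = "dottask_spec_error")
  expect_error(trial_spec("two_dot", 1, lab), class = "dottask_spec_error")
  expect_error(trial_spec("two_number_dot", 1, two), class = "dottask_spec_error")
  expect_error(trial_spec("two_number_dot", 1, lab, forced = TRUE),
               class = "dottask_spec_error")
  expect_error(trial_spec("dot_probe", 1, one), class = "dottask_spec_error")
})

test_that("two_number_dot state machine: order decides the outcome", {
  set.seed(21)
  sp <- choice_trial_spec()
  d1 <- label_of(sp$stimuli, "1"); d2 <- label_of(sp$stimuli, "2")

  wrong <- run_trial(sp, scripted_agent(list(at_dot(d2))))
  expect_equal(wrong$result$outcome, "incorrect")
  expect_false(wrong$result$rewarded)
  expect_equal(vapply(wrong$events, `[[`, "", "kind"), c("buzzer", "led_red"))

  right <- run_trial(sp, scripted_agent(list(at_dot(d1), at_dot(d2))))
  expect_equal(right$result$outcome, "correct")
  expect_true(right$result$rewarded)
  expect_equal(vapply(right$events, `[[`, "", "kind"),
               c("chime", "led_green", "pellet"))
  expect_equal(right$result$end_s, 2)           # two 1-s touches
  expect_equal(right$result$response_latency_s, 1)
})

test_that("two_dot is order-free; one_dot ends on first hit", {
  set.seed(22)
  stim <- sample_dot_placement(screen_spec(), c(100, 100))
  sp <- trial_spec("two_dot", 1, stim)
  for (ord in list(1:2, 2:1)) {
    out <- run_trial(sp, scripted_agent(list(at_dot(stim[[ord[1]]]),
                                             at_dot(stim[[ord[2]]]))))
    expect_equal(out$result$outcome, "correct")
    expect_equal(vapply(out$events, `[[`, "", "kind"),
                 c("chime", "led_green", "pellet"))
  }
  one <- sample_dot_placement(screen_spec(), 200)
  out <- run_trial(trial_spec("one_dot", 1, one),
                   scripted_agent(list(at_dot(one[[1]]))))
  expect_equal(out$result$outcome, "correct")
  expect_length(out$result$touches, 1)
})

test_that("forced trials admit no error path and background misses are inert", {
  set.seed(23)
  spf <- choice_trial_spec(forced = TRUE)
  out <- run_trial(spf, scripted_agent(list(at_dot(spf$stimuli[[1]]))))
  expect_equal(out$result$outcome, "correct")
  expect_true(out$result$forced)
  expect_true(out$result$rewarded)

  # a miss is logged but changes nothing; the later hit still wins
  sp <- choice_trial_spec()
  d1 <- label_of(sp$stimuli, "1"); d2 <- label_of(sp$stimuli, "2")
  miss_x <- if (min(d1$center_x_px, d2$center_x_px) > 120) 1 else 1023
  out <- run_trial(sp, scripted_agent(list(c(1, miss_x, 1),
                                           at_dot(d1), at_dot(d2))))
  expect_equal(out$result$outcome, "correct")
  expect_length(out$result$touches, 3)
  expect_true(is.na(out$result$touches[[1]]$hit))
  expect_equal(out$result$response_latency_s, 1)  # first touch, hit or not
})

test_that("untouched trials abort with no feedback", {
  set.seed(24)
  sp <- choice_trial_spec()
  out <- run_trial(sp, never_touch_agent(), onset_s = 10,
                   max_trial_duration_s = 60)
  expect_equal(out$result$outcome, "aborted")
  expect_false(out$result$rewarded)
  expect_length(out$events, 0)
  expect_equal(out$result$end_s, 70)
  expect_true(is.na(out$result$response_latency_s))
})

test_that("ideal One Dot session realizes the 4-second trial cycle", {
  stage <- curriculum_stage("one_dot", 1, dot_diameter_px = 100)
  log <- run_session(session_spec(1, stage, seed = 25), ideal_agent())
  expect_length(log$trials, 150)
  onsets <- vapply(log$trials, function(tr) tr$onset_s, numeric(1))
  expect_equal(onsets, (seq_len(150) - 1) * 4.0)
  expect_true(all(vapply(log$trials, function(tr) tr$outcome, "") == "correct"))
  expect_equal(log$events[[1]]$kind, "session_start_chime")
  expect_equal(log$events[[1]]$time_s, 0)
})

test_that("a never-touching subject yields only aborted trials", {
  stage <- curriculum_stage("one_dot", 1)
  log <- run_session(session_spec(1, stage, seed = 26), never_touch_agent())
  outs <- vapply(log$trials, function(tr) tr$outcome, "")
  expect_true(all(outs == "aborted"))
  expect_length(log$trials, 10)  # 60-s timeouts + 3-s ITIs in 600 s
  expect_equal(trials_per_minute(log), 0)
})

test_that("sessions are reproducible given seed and agent", {
  stage <- curriculum_stage("two_number_dot", 1, forced_fraction = 0.25)
  a <- run_session(session_spec(1, stage, seed = 27),
                   stimulus_directed_random_agent())
  b <- run_session(session_spec(1, stage, seed = 27),
                   stimulus_directed_random_agent())
  expect_identical(session_log_records(a), session_log_records(b))
  c <- run_session(session_spec(1, stage, seed = 28),
                   stimulus_directed_random_agent())
  expect_false(identical(session_log_records(a), session_log_records(c)))
})

test_that("a trial in flight at the session cutoff completes", {
  stage <- curriculum_stage("one_dot", 1)
  log <- run_session(session_spec(1, stage, duration_s = 601, iti_s = 1,
                                  seed = 29), ideal_agent(latency_s = 7))
  last <- log$trials[[length(log$trials)]]
  expect_lt(last$onset_s, 601)
  expect_gt(last$end_s, 601)          # allowed to finish past the cutoff
  expect_equal(last$outcome, "correct")
})

test_that("session queues run in order with isolated clocks", {
  cur <- build_training_curriculum()
  specs <- curriculum_session_specs(cur, 1:10, base_seed = 100)
  logs <- run_session_queue(specs, ideal_agent())
  expect_length(logs, 10)
  expect_true(all(vapply(logs, function(l) l$metadata$task, "") == "one_dot"))
  expect_equal(vapply(logs, function(l) l$metadata$session_index, 1L), 1:10)
  expect_true(all(vapply(logs, function(l) l$trials[[1]]$onset_s, 1) == 0))
  expect_identical(run_session_queue(list(), ideal_agent()), list())
})

test_that("pellets are conserved: one per correct trial, any agent", {
  set.seed(30)
  agents <- list(ideal_agent(), stimulus_directed_random_agent(),
                 random_location_agent(latency_mean_s = 0.3),
                 rescorla_wagner_agent())
  stages <- list(curriculum_stage("one_dot", 1),
                 curriculum_stage("two_dot", 1),
                 curriculum_stage("two_number_dot", 1, forced_fraction = 0.25))
  for (ag in agents) for (st in stages) {
    log <- run_session(session_spec(1, st, duration_s = 120,
                                    seed = sample.int(1e6, 1)), ag)
    pellets <- sum(vapply(log$events, function(e) e$kind == "pellet", NA))
    correct <- sum(vapply(log$trials, function(tr) tr$outcome == "correct", NA))
    expect_identical(pellets, correct)
  }
})

test_that("trial throughput is monotone in ITI and agent latency", {
  stage <- curriculum_stage("one_dot", 1)
  n_at <- function(iti, lat) length(run_session(
    session_spec(1, stage, duration_s = 300, iti_s = iti, seed = 31),
    ideal_agent(latency_s = lat))$trials)
  by_iti <- vapply(c(0, 1, 3, 10), n_at, 1L, lat = 1)
  expect_true(all(diff(by_iti) <= 0))
  by_lat <- vapply(c(0.2, 1, 2, 5), n_at, 1L, iti = 3)
  expect_true(all(diff(by_lat) <= 0))
})

test_that("every generated log satisfies the session-log schema", {
  set.seed(32)
  stage <- curriculum_stage("two_number_dot", 1, forced_fraction = 0.25)
  for (ag in list(stimulus_directed_random_agent(), rescorla_wagner_agent())) {
    log <- run_session(session_spec(3, stage, duration_s = 200, seed = 33), ag)
    expect_equal(log$events[[1]]$kind, "session_start_chime")
    onsets <- vapply(log$trials, function(tr) tr$onset_s, 1)
    expect_true(all(diff(onsets) > 0))
    expect_true(all(onsets < log$spec$duration_s))
    ends <- vapply(log$trials, function(tr) tr$end_s, 1)
    expect_true(all(ends >= onsets))
    forced <- vapply(log$trials, function(tr) tr$forced, NA)
    outs <- vapply(log$trials, function(tr) tr$outcome, "")
    expect_true(all(outs[forced] == "correct"))
  }
})

test_that("degenerate timing is bounded by the clock tick", {
  stage <- curriculum_stage("one_dot", 1)
  log <- run_session(session_spec(1, stage, duration_s = 0.05, iti_s = 0,
                                  seed = 34), ideal_agent(latency_s = 0))
  expect_length(log$trials, 50)  # one trial per millisecond tick
})
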