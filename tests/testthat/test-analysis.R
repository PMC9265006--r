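test_that("trials_per_minute divides completed trials by session minutes", {
  stage <- curriculum_stage("one_dot", 1)
  log <- run_session(session_spec(1, stage, seed = 81), ideal_agent())
  expect_equal(trials_per_minute(log), 15.0)
  empty <- run_session(session_spec(1, stage, seed = 82), never_touch_agent())
  expect_equal(trials_per_minute(empty), 0.0)
  # record-level arithmetic: 37 completed trials in 600 s
  set.seed(83)
  rec <- random_trial_records(50)
  rec$outcome <- c(rep("correct", 30), rep("incorrect", 7), rep("aborted", 13))
  rec$forced <- 0L
  rec$rewarded <- as.integer(rec$outcome == "correct")
  expect_equal(trials_per_minute(rec, duration_s = 600), 3.7)
})

test_that("engagement_table reports first/last-session rates per task", {
  cur <- build_training_curriculum()
  specs <- curriculum_session_specs(cur, c(1, 10, 11, 15), base_seed = 200)
  logs <- run_session_queue(specs, ideal_agent())
  tab <- engagement_table(logs)
  expect_setequal(tab$task, c("one_dot", "two_dot"))
  od <- tab[tab$task == "one_dot", ]
  expect_equal(od$first_session, 1); expect_equal(od$last_session, 10)
  expect_equal(od$first_trials_per_min, 15.0)
  expect_equal(od$last_trials_per_min, 15.0)
  # absent tasks are omitted; a single session is its own first and last
  single <- engagement_table(logs[1])
  expect_equal(nrow(single), 1)
  expect_equal(single$first_trials_per_min, single$last_trials_per_min)
  expect_error(engagement_table(list()), class = "dottask_spec_error")
})

test_that("the exact binomial test matches closed forms and binom.test", {
  expect_equal(binomial_test_vs_chance(1, 1), 0.5)
  expect_equal(binomial_test_vs_chance(2, 2), 0.25)
  # independent enumeration oracle for the 30/40 upper tail
  oracle <- sum(exp(lchoose(40, 30:40))) / 2^40
  expect_equal(binomial_test_vs_chance(30, 40), oracle, tolerance = 1e-14)
  # spot-check both sidedness settings against stats::binom.test
  set.seed(84)
  for (i in 1:25) {
    n <- sample(1:60, 1); k <- sample(0:n, 1)
    p0 <- runif(1, 0.2, 0.8)
    expect_equal(binomial_test_vs_chance(k, n, p0, "greater"),
                 stats::binom.test(k, n, p0, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(binomial_test_vs_chance(k, n, p0, "two_sided"),
                 stats::binom.test(k, n, p0, alternative = "two.sided")$p.value,
                 tolerance = 1e-12)
  }
  expect_error(binomial_test_vs_chance(5, 4), class = "dottask_spec_error")
  expect_error(binomial_test_vs_chance(-1, 4), class = "dottask_spec_error")
})

test_that("block_performance pools choice trials and excludes forced/aborted", {
  # one 5-session block: 50 trials/session, 10 forced, 2 aborted, 30 correct
  # among the 38 completed choice trials
  make_session <- function(si) {
    rec <- random_trial_records(50, session_index = si)
    rec$task <- "two_number_dot"
    rec$forced <- rep(c(1L, 0L, 0L, 0L, 0L), 10)
    rec$outcome <- "incorrect"
    rec$outcome[rec$forced == 1L] <- "correct"
    choice_idx <- which(rec$forced == 0L)
    rec$outcome[choice_idx[1:2]] <- "aborted"
    rec$outcome[choice_idx[3:32]] <- "correct"
    rec$rewarded <- as.integer(rec$outcome == "correct")
    rec$n_touches[rec$outcome == "aborted"] <- 0L
    rec$response_latency_s[rec$outcome == "aborted"] <- NA_real_
    rec$n_touches[rec$outcome != "aborted"] <- pmax(rec$n_touches[rec$outcome != "aborted"], 1L)
    rec
  }
  set.seed(85)
  rec <- do.call(rbind, lapply(1:5, make_session))
  bp <- block_performance(rec)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$n_choice_trials, 5 * 38)
  expect_equal(bp$n_correct, 5 * 30)
  expect_equal(bp$proportion_correct, 150 / 190)
  expect_equal(bp$p_value, binomial_test_vs_chance(150, 190))
  expect_false(bp$partial)

  # trailing partial block is flagged; all-forced block reports missing
  rec7 <- do.call(rbind, lapply(1:7, make_session))
  bp7 <- block_performance(rec7)
  expect_equal(nrow(bp7), 2)
  expect_true(bp7$partial[2])
  expect_equal(bp7$session_start, c(1, 6))
  expect_equal(bp7$session_end, c(5, 7))

  allf <- random_trial_records(20, session_index = 1)
  allf$task <- "two_number_dot"
  allf$forced <- 1L; allf$outcome <- "correct"; allf$rewarded <- 1L
  allf$n_touches <- pmax(allf$n_touches, 1L)
  allf$response_latency_s[is.na(allf$response_latency_s)] <- 0.5
  bpf <- block_performance(allf)
  expect_true(is.na(bpf$proportion_correct))
  expect_true(is.na(bpf$p_value))
  expect_equal(bpf$n_choice_trials, 0)
})

test_that("block flags mirror a learning trajectory through the engine", {
  # a converged learner is flagged above chance in every block and the flag
  # persists once accuracy clears the critical proportion
  stage <- curriculum_stage("two_number_dot", 1, forced_fraction = 0.25)
  ag <- rescorla_wagner_agent()
  logs <- lapply(1:10, function(i)
    run_session(session_spec(i, stage, duration_s = 120, seed = 300 + i), ag))
  bp <- block_performance(logs, analysis_config(block_size_sessions = 2))
  first_flag <- which(bp$above_chance)[1]
  expect_false(is.na(first_flag))
  expect_true(all(bp$above_chance[first_flag:nrow(bp)]))
})

test_that("analysis_config validates and drives sidedness", {
  expect_error(analysis_config(block_size_sessions = 0),
               class = "dottask_spec_error")
  expect_error(analysis_config(chance_level = 1.2), "chance_level")
  cfg2 <- analysis_config(test_sidedness = "two_sided")
  set.seed(86)
  rec <- random_trial_records(40)
  rec$task <- "two_number_dot"; rec$forced <- 0L
  rec$outcome <- rep(c("correct", "incorrect"), each = 20)
  rec$rewarded <- as.integer(rec$outcome == "correct")
  rec$n_touches <- pmax(rec$n_touches, 1L)
  rec$response_latency_s[is.na(rec$response_latency_s)] <- 0.5
  b1 <- block_performance(rec, analysis_config())
  b2 <- block_performance(rec, cfg2)
  expect_equal(b1$p_value, binomial_test_vs_chance(20, 40, sidedness = "greater"))
  expect_equal(b2$p_value, binomial_test_vs_chance(20, 40, sidedness = "two_sided"))
})
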