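#' Analysis configuration
#'
#' Defaults mirror the training study's analysis: performance pooled over
#' blocks of five sessions, tested one-sided against a 0.5 chance level at
#' alpha = 0.05.
#'
#' @param block_size_sessions Sessions per performance block (default 5).
#' @param chance_level Chance accuracy for the choice task (default 0.5,
#'   i.e. a uniform pick between two ordered dots).
#' @param test_sidedness `"greater"` (is performance above chance?) or
#'   `"two_sided"`.
#' @param alpha Significance level for the above-chance flag (default 0.05).
#' @return Object of class `dot_analysis_config`.
#' @export
analysis_config <- function(block_size_sessions = 5L, chance_level = 0.5,
                            test_sidedness = c("greater", "two_sided"),
                            alpha = 0.05) {
  block_size_sessions <- check_count(block_size_sessions,
                                     "block_size_sessions", min = 1L)
  check_number(chance_level, "chance_level", min = 0, strict_min = TRUE)
  if (chance_level >= 1) dt_spec_error("`chance_level` must be < 1")
  check_number(alpha, "alpha", min = 0, max = 1)
  structure(list(block_size_sessions = block_size_sessions,
                 chance_level = chance_level,
                 test_sidedness = match.arg(test_sidedness),
                 alpha = alpha),
            class = "dot_analysis_config")
}

#' Trials completed per minute
#'
#' The engagement proxy: completed (non-aborted) trials divided by the
#' session length in minutes.
#'
#' @param log A `dot_session_log`, or a trial record data frame for a
#'   single session paired with `duration_s`.
#' @param duration_s Session length in seconds (taken from the log when a
#'   `dot_session_log` is given).
#' @return Rate in trials per minute.
#' @export
trials_per_minute <- function(log, duration_s = NULL) {
  if (inherits(log, "dot_session_log")) {
    duration_s <- log$spec$duration_s
    n <- sum(vapply(log$trials, function(tr) tr$outcome != "aborted",
                    logical(1)))
  } else {
    if (is.null(duration_s))
      dt_spec_error("`duration_s` is required with record input")
    n <- sum(log$outcome != "aborted")
  }
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  n / (duration_s / 60)
}

records_from_logs <- function(logs) {
  if (is.data.frame(logs)) return(logs)
  if (inherits(logs, "dot_session_log")) logs <- list(logs)
  do.call(rbind, lapply(logs, session_log_records))
}

#' Engagement table: first vs last session per task
#'
#' For each task present in the logs, reports the trials-per-minute rate at
#' that task's first and last session index.
#'
#' @param logs List of `dot_session_log` objects.
#' @return Data frame with columns `task`, `first_session`, `last_session`,
#'   `first_trials_per_min`, `last_trials_per_min`; tasks absent from the
#'   logs are omitted.
#' @export
engagement_table <- function(logs) {
  if (inherits(logs, "dot_session_log")) logs <- list(logs)
  if (!length(logs)) dt_spec_error("`logs` must contain at least one session")
  task <- vapply(logs, function(l) l$metadata$task, character(1))
  sess <- vapply(logs, function(l) l$metadata$session_index, integer(1))
  rate <- vapply(logs, trials_per_minute, numeric(1))
  out <- lapply(intersect(TASKS, unique(task)), function(tk) {
    i <- which(task == tk)
    fi <- i[which.min(sess[i])]; li <- i[which.max(sess[i])]
    data.frame(task = tk, first_session = sess[fi], last_session = sess[li],
               first_trials_per_min = rate[fi], last_trials_per_min = rate[li])
  })
  do.call(rbind, out)
}

#' Exact binomial test against chance
#'
#' Exact test by direct summation of binomial point probabilities — no
#' normal approximation. One-sided `"greater"` sums the upper tail
#' `P(X >= n_correct)`; `"two_sided"` sums all outcomes whose point
#' probability does not exceed that of the observed count (the standard
#' exact two-sided convention).
#'
#' @param n_correct Number of correct choice trials.
#' @param n Number of choice trials (>= 1).
#' @param chance Chance success probability (default 0.5).
#' @param sidedness `"greater"` or `"two_sided"`.
#' @return The p-value.
#' @examples
#' binomial_test_vs_chance(30, 40)
#' @export
binomial_test_vs_chance <- function(n_correct, n, chance = 0.5,
                                    sidedness = c("greater", "two_sided")) {
  sidedness <- match.arg(sidedness)
  n <- check_count(n, "n", min = 1L)
  n_correct <- check_count(n_correct, "n_correct", min = 0L)
  if (n_correct > n) dt_spec_error("`n_correct` must be <= `n`")
  check_number(chance, "chance", min = 0, strict_min = TRUE)
  if (chance >= 1) dt_spec_error("`chance` must be < 1")
  probs <- stats::dbinom(0:n, n, chance)
  p <- if (sidedness == "greater") {
    sum(probs[(n_correct + 1L):(n + 1L)])
  } else {
    # relative tolerance guards against FP noise in the equality comparison
    sum(probs[probs <= probs[n_correct + 1L] * (1 + 1e-7)])
  }
  min(p, 1)
}

#' Block-wise choice performance
#'
#' Pools choice trials over consecutive non-overlapping blocks of sessions
#' and tests each block's accuracy against chance with the exact binomial
#' test. Forced-choice trials (always correct by construction) and aborted
#' trials are excluded. A block with zero choice trials gets missing
#' proportion and p-value, not zeros.
#'
#' @param logs List of `dot_session_log` objects for the sequencing task,
#'   in session order — or an equivalent trial record data frame.
#' @param cfg An [analysis_config()].
#' @return Data frame of class `dot_block_performance`: `block_index`,
#'   `session_start`, `session_end`, `n_sessions`, `partial` (trailing
#'   short block), `n_choice_trials`, `n_correct`, `proportion_correct`,
#'   `p_value`, `above_chance` (`p <= alpha`).
#' @export
block_performance <- function(logs, cfg = analysis_config()) {
  rec <- records_from_logs(logs)
  rec <- rec[rec$task == "two_number_dot", , drop = FALSE]
  if (!nrow(rec)) dt_spec_error("no two_number_dot trials in input")
  sessions <- sort(unique(rec$session_index))
  bs <- cfg$block_size_sessions
  n_blocks <- ceiling(length(sessions) / bs)
  out <- lapply(seq_len(n_blocks), function(b) {
    sb <- sessions[((b - 1L) * bs + 1L):min(b * bs, length(sessions))]
    rb <- rec[rec$session_index %in% sb, , drop = FALSE]
    choice <- rb[rb$forced == 0L & rb$outcome != "aborted", , drop = FALSE]
    n <- nrow(choice)
    k <- sum(choice$outcome == "correct")
    if (n == 0L) {
      prop <- NA_real_; p <- NA_real_; above <- NA
    } else {
      prop <- k / n
      p <- binomial_test_vs_chance(k, n, cfg$chance_level, cfg$test_sidedness)
      above <- p <= cfg$alpha
    }
    data.frame(block_index = b, session_start = min(sb),
               session_end = max(sb), n_sessions = length(sb),
               partial = length(sb) < bs, n_choice_trials = n,
               n_correct = k, proportion_correct = prop, p_value = p,
               above_chance = above)
  })
  structure(do.call(rbind, out),
            class = c("dot_block_performance", "data.frame"))
}

#' Plot block performance
#'
#' Proportion correct per session block with the chance level and
#' above-chance flags marked (base graphics).
#'
#' @param x A `dot_block_performance` table.
#' @param chance_level Reference line (default 0.5).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.dot_block_performance <- function(x, chance_level = 0.5, ...) {
  plot(x$block_index, x$proportion_correct, type = "b", ylim = c(0, 1),
       xlab = "Session block", ylab = "Proportion correct (choice trials)",
       pch = ifelse(isTRUE(x$above_chance) | x$above_chance %in% TRUE, 19, 1),
       ...)
  graphics::abline(h = chance_level, lty = 2)
  invisible(x)
}
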