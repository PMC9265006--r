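# Agent interface: a `dot_agent` is a list with
#   next_touch(visible, screen, time_s) -> list(latency_s, x_px, y_px) | NULL
#   notify_trial_outcome(result)        -> called after every trial (optional)
#   reset()                             -> clears transient per-trial state
#                                          (never learned values)
# Agents draw from R's global RNG; run_session() seeds it per session, so a
# seeded session with any agent below is fully reproducible.

new_agent <- function(kind, next_touch, notify_trial_outcome = NULL,
                      reset = NULL, state = NULL) {
  structure(list(kind = kind, next_touch = next_touch,
                 notify_trial_outcome = notify_trial_outcome,
                 reset = reset, state = state),
            class = "dot_agent")
}

#' @export
print.dot_agent <- function(x, ...) {
  cat("<dot_agent>", x$kind, "\n"); invisible(x)
}

draw_latency <- function(mean_s, jitter_s) {
  if (jitter_s <= 0) return(mean_s)
  max(mean_s + stats::runif(1, -jitter_s, jitter_s), 0)
}

# visible dot to aim for under "lowest numeral first" (labels sort
# "1" < "2" < "none"; ties broken by list order)
required_dot <- function(visible) {
  labs <- vapply(visible, function(s) s$label, character(1))
  ord <- match(labs, c("1", "2", "none"))
  visible[[which.min(ord)]]
}

# uniform point inside a dot's disc
point_in_dot <- function(dot) {
  r <- dot$diameter_px / 2 * sqrt(stats::runif(1))
  a <- stats::runif(1, 0, 2 * pi)
  list(x = dot$center_x_px + r * cos(a), y = dot$center_y_px + r * sin(a))
}

#' Ideal (zero-decision) agent
#'
#' Always touches the currently required stimulus — the lowest numeral
#' first, so it is always correct — after a fixed latency. With the default
#' 1-second touch latency and 3-second inter-trial interval it realizes the
#' engine's throughput ceiling of 15 trials per minute on One Dot.
#'
#' @param latency_s Fixed seconds from query to touch (default 1.0).
#' @return A `dot_agent`.
#' @export
ideal_agent <- function(latency_s = 1.0) {
  check_number(latency_s, "latency_s", min = 0)
  new_agent("ideal", function(visible, screen, time_s) {
    d <- required_dot(visible)
    list(latency_s = latency_s, x_px = d$center_x_px, y_px = d$center_y_px)
  })
}

#' Stimulus-directed random agent
#'
#' Touches a uniformly chosen visible dot, at a uniform point within it,
#' after a stochastic latency. On two-alternative choice trials this is the
#' chance-level oracle: exactly 50% of its first touches land on "1".
#'
#' @param latency_mean_s,latency_jitter_s Latency model: fixed mean plus
#'   uniform jitter on `[-jitter, +jitter]`, truncated at 0.
#' @return A `dot_agent`.
#' @export
stimulus_directed_random_agent <- function(latency_mean_s = 1.0,
                                           latency_jitter_s = 0.5) {
  new_agent("stimulus_random", function(visible, screen, time_s) {
    d <- visible[[sample.int(length(visible), 1L)]]
    p <- point_in_dot(d)
    list(latency_s = draw_latency(latency_mean_s, latency_jitter_s),
         x_px = p$x, y_px = p$y)
  })
}

#' Random-location agent
#'
#' Touches uniformly random screen points, oblivious to the stimuli; its
#' per-touch hit probability on a dot of diameter d equals the area
#' fraction pi (d/2)^2 / (width x height). Models unengaged background
#' touching.
#'
#' @inheritParams stimulus_directed_random_agent
#' @return A `dot_agent`.
#' @export
random_location_agent <- function(latency_mean_s = 1.0,
                                  latency_jitter_s = 0.5) {
  new_agent("random_location", function(visible, screen, time_s) {
    list(latency_s = draw_latency(latency_mean_s, latency_jitter_s),
         x_px = stats::runif(1, 0, screen$width_px),
         y_px = stats::runif(1, 0, screen$height_px))
  })
}

rw_p1 <- function(v, w, beta) 1 / (1 + exp(-beta * (v - w)))

#' Rescorla-Wagner learning agent
#'
#' A minimal two-action learner for the sequencing task. On each choice
#' trial it picks the action "touch-1-first" with softmax probability
#' `P = exp(beta v) / (exp(beta v) + exp(beta w))` where `v` and `w` are the
#' current values of touching "1" first and "2" first; after the trial the
#' chosen action's value is updated by `value <- value + alpha (r - value)`
#' with reward `r` in `{0, 1}`. Forced-choice trials (only the "1" dot
#' shown) always reward and update the "touch-1-first" value — the
#' mechanism by which forced trials scaffold learning. On non-sequencing
#' tasks the agent simply touches the required dot.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param beta Softmax inverse temperature (>= 0).
#' @param v0,w0 Initial action values for "touch-1-first" / "touch-2-first".
#' @inheritParams stimulus_directed_random_agent
#' @return A `dot_agent`. Learned values persist across sessions in a
#'   queue; inspect them via `agent$state$v` / `agent$state$w`.
#' @export
rescorla_wagner_agent <- function(alpha = 0.1, beta = 5, v0 = 0.5, w0 = 0.5,
                                  latency_mean_s = 1.0,
                                  latency_jitter_s = 0.5) {
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(beta, "beta", min = 0)
  st <- new.env(parent = emptyenv())
  st$v <- v0; st$w <- w0
  st$pending <- NULL  # "1" or "2" = chosen first-touch on a choice trial

  next_touch <- function(visible, screen, time_s) {
    labs <- vapply(visible, function(s) s$label, character(1))
    lat <- draw_latency(latency_mean_s, latency_jitter_s)
    target <- if (setequal(labs, c("1", "2"))) {
      # choice-trial onset: commit to an action
      st$pending <- if (stats::runif(1) < rw_p1(st$v, st$w, beta)) "1" else "2"
      visible[[match(st$pending, labs)]]
    } else {
      required_dot(visible)
    }
    p <- point_in_dot(target)
    list(latency_s = lat, x_px = p$x, y_px = p$y)
  }

  notify <- function(result) {
    if (result$task == "two_number_dot") {
      if (result$forced) {
        st$v <- st$v + alpha * (1 - st$v)
      } else if (!is.null(st$pending) && result$outcome != "aborted") {
        r <- as.numeric(result$rewarded)
        if (st$pending == "1") st$v <- st$v + alpha * (r - st$v)
        else st$w <- st$w + alpha * (r - st$w)
      }
    }
    st$pending <- NULL
  }

  new_agent("rescorla_wagner", next_touch, notify,
            reset = function() st$pending <- NULL, state = st)
}

#' Fast Rescorla-Wagner choice simulation
#'
#' Simulates the learning agent's choice sequence on the sequencing task
#' without screen geometry or timing: each choice trial draws the action
#' from the softmax, is rewarded iff "touch-1-first" was chosen, and
#' updates the chosen value; forced trials reward and update
#' "touch-1-first". Identical value dynamics to [rescorla_wagner_agent()]
#' run through the engine, at a fraction of the cost — used for
#' Monte-Carlo studies of learning curves.
#'
#' @inheritParams rescorla_wagner_agent
#' @param n_trials Number of trials.
#' @param forced Logical vector (recycled) marking forced trials.
#' @return Data frame with one row per trial: `forced`, `action` ("1" or
#'   "2"; NA on forced trials), `correct` (0/1; 1 on forced trials),
#'   `p1` (softmax probability of "touch-1-first" before the trial).
#' @export
simulate_rw_choices <- function(alpha = 0.1, beta = 5, v0 = 0.5, w0 = 0.5,
                                n_trials = 1000L, forced = FALSE) {
  n_trials <- check_count(n_trials, "n_trials", min = 0L)
  forced <- rep_len(as.logical(forced), n_trials)
  v <- v0; w <- w0
  action <- character(n_trials); correct <- integer(n_trials)
  p1 <- numeric(n_trials)
  u <- stats::runif(n_trials)
  for (k in seq_len(n_trials)) {
    p1[k] <- rw_p1(v, w, beta)
    if (forced[k]) {
      action[k] <- NA_character_; correct[k] <- 1L
      v <- v + alpha * (1 - v)
    } else if (u[k] < p1[k]) {
      action[k] <- "1"; correct[k] <- 1L
      v <- v + alpha * (1 - v)
    } else {
      action[k] <- "2"; correct[k] <- 0L
      w <- w + alpha * (0 - w)
    }
  }
  data.frame(forced = forced, action = action, correct = correct, p1 = p1)
}

#' Log-likelihood of a Rescorla-Wagner parameterization
#'
#' Computes the choice log-likelihood of an observed sequence under given
#' `(alpha, beta)`, replaying the value dynamics (forced trials update but
#' contribute no likelihood term, having no choice).
#'
#' @param choices Data frame as returned by [simulate_rw_choices()]
#'   (columns `forced`, `action`).
#' @inheritParams rescorla_wagner_agent
#' @return Scalar log-likelihood.
#' @export
rw_loglik <- function(choices, alpha, beta, v0 = 0.5, w0 = 0.5) {
  v <- v0; w <- w0; ll <- 0
  for (k in seq_len(nrow(choices))) {
    if (choices$forced[k]) {
      v <- v + alpha * (1 - v)
      next
    }
    p1 <- rw_p1(v, w, beta)
    if (choices$action[k] == "1") {
      ll <- ll + log(p1)
      v <- v + alpha * (1 - v)
    } else {
      ll <- ll + log(1 - p1)
      w <- w + alpha * (0 - w)
    }
  }
  ll
}

#' Recover learning parameters by likelihood grid search
#'
#' Maximizes [rw_loglik()] over a rectangular `(alpha, beta)` grid — the
#' standard synthetic-recovery check that simulated choice data identify
#' the generating parameters to within the grid resolution.
#'
#' @inheritParams rw_loglik
#' @param alpha_grid,beta_grid Candidate values.
#' @return List with `alpha`, `beta` (maximizers) and `loglik`.
#' @export
fit_rw_grid <- function(choices, alpha_grid = seq(0.02, 0.3, by = 0.02),
                        beta_grid = seq(1, 10, by = 1),
                        v0 = 0.5, w0 = 0.5) {
  best <- list(alpha = NA_real_, beta = NA_real_, loglik = -Inf)
  for (a in alpha_grid) for (b in beta_grid) {
    ll <- rw_loglik(choices, a, b, v0, w0)
    if (ll > best$loglik) best <- list(alpha = a, beta = b, loglik = ll)
  }
  best
}

#' Construct an agent by name
#'
#' CLI-facing factory: `"ideal"`, `"stimulus-random"`, `"random-location"`,
#' or `"rw"`, with parameters forwarded to the constructor.
#'
#' @param name Agent name.
#' @param ... Passed to the corresponding constructor.
#' @return A `dot_agent`.
#' @export
agent_from_name <- function(name, ...) {
  switch(name,
    "ideal"            = ideal_agent(...),
    "stimulus-random"  = stimulus_directed_random_agent(...),
    "random-location"  = random_location_agent(...),
    "rw"               = rescorla_wagner_agent(...),
    dt_config_error(sprintf("unknown agent '%s'", name))
  )
}
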