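# A dot_agent is structurally a list with a next_touch() function (see
# R/agents.R); tests build bare ones to script exact touch sequences.

scripted_agent <- function(steps) {
  i <- 0L
  structure(list(
    kind = "scripted",
    next_touch = function(visible, screen, time_s) {
      i <<- i + 1L
      if (i > length(steps) || is.null(steps[[i]])) return(NULL)
      s <- steps[[i]]
      list(latency_s = s[1], x_px = s[2], y_px = s[3])
    }), class = "dot_agent")
}

never_touch_agent <- function() {
  structure(list(kind = "never",
                 next_touch = function(visible, screen, time_s) NULL),
            class = "dot_agent")
}

# touch step aimed at a stimulus center
at_dot <- function(dot, latency = 1) c(latency, dot$center_x_px, dot$center_y_px)

choice_trial_spec <- function(screen = screen_spec(), forced = FALSE,
                              trial_index = 1) {
  stim <- if (forced)
    sample_dot_placement(screen, 100, labels = "1")
  else
    sample_dot_placement(screen, c(100, 100), labels = c("1", "2"))
  trial_spec("two_number_dot", trial_index, stim, forced = forced)
}

label_of <- function(stimuli, lab) {
  stimuli[[which(vapply(stimuli, function(s) s$label, character(1)) == lab)]]
}
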