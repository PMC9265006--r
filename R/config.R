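#' Default protocol configuration
#'
#' The full stated protocol as a plain list, serializable to JSON: screen
#' geometry, session timing, the 95-session curriculum, and analysis
#' settings.
#'
#' @return Nested list with sections `screen`, `timing`, `curriculum`,
#'   `analysis`.
#' @export
default_config <- function() {
  cur <- build_training_curriculum()
  list(
    screen = list(width_px = 1024L, height_px = 768L, min_gap_px = 0),
    timing = list(duration_s = 600, iti_s = 3, max_trial_duration_s = 60),
    curriculum = lapply(cur$stages, unclass),
    analysis = list(block_size_sessions = 5L, chance_level = 0.5,
                    test_sidedness = "greater", alpha = 0.05)
  )
}

#' Write / read a JSON protocol configuration
#'
#' @param config List as produced by [default_config()].
#' @param path JSON file path.
#' @return `write_config()`: `path`, invisibly. `read_config()`: the
#'   config list, with constructors re-validating each section.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) dt_parse_error(
                    sprintf("%s: invalid JSON (%s)", path, conditionMessage(e))))
  for (sec in c("screen", "timing", "curriculum", "analysis"))
    if (is.null(cfg[[sec]]))
      dt_config_error(sprintf("%s: missing config section '%s'", path, sec))
  cfg
}

#' Materialize config sections into package objects
#'
#' @param config A config list from [read_config()].
#' @return `config_screen()`: a [screen_spec()]. `config_curriculum()`: a
#'   `dot_curriculum`. `config_analysis()`: an [analysis_config()].
#' @export
config_screen <- function(config) {
  screen_spec(config$screen$width_px, config$screen$height_px)
}

#' @rdname config_screen
#' @export
config_curriculum <- function(config) {
  new_curriculum(lapply(config$curriculum, function(st)
    curriculum_stage(st$task, st$n_sessions,
                     dot_diameter_px = st$dot_diameter_px %||% 100,
                     forced_fraction = st$forced_fraction %||% 0)))
}

#' @rdname config_screen
#' @export
config_analysis <- function(config) {
  a <- config$analysis
  analysis_config(a$block_size_sessions %||% 5L, a$chance_level %||% 0.5,
                  a$test_sidedness %||% "greater", a$alpha %||% 0.05)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
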