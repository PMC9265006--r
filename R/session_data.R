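#' Column order of the trial-log CSV
#'
#' One flat record per trial; dot 2 columns are empty on single-dot trials
#' and `response_latency_s` is empty when the trial drew no touch. Times
#' are on the session clock, recorded to millisecond precision.
#'
#' @return Character vector of column names, in file order.
#' @export
trial_log_columns <- function() c(
  "group_id", "session_index", "task", "trial_index", "forced", "outcome",
  "rewarded", "onset_s", "end_s", "response_latency_s", "n_touches",
  "dot1_x", "dot1_y", "dot1_diam", "dot1_label",
  "dot2_x", "dot2_y", "dot2_diam", "dot2_label",
  "first_touch_x", "first_touch_y")

round_ms <- function(x) round(x, 3)

#' Flatten a session log to trial records
#'
#' @param log A `dot_session_log` from [run_session()].
#' @return Data frame with the columns of [trial_log_columns()], one row
#'   per trial, times rounded to the millisecond.
#' @export
session_log_records <- function(log) {
  trials <- log$trials
  n <- length(trials)
  get <- function(f) vapply(trials, f, numeric(1))
  dot_field <- function(i, f, default) vapply(trials, function(tr) {
    if (length(tr$stimuli) >= i) f(tr$stimuli[[i]]) else default
  }, if (is.character(default)) character(1) else numeric(1))
  first_touch <- function(f) vapply(trials, function(tr) {
    if (length(tr$touches)) f(tr$touches[[1L]]) else NA_real_
  }, numeric(1))

  data.frame(
    group_id = rep(log$metadata$group_id, n),
    session_index = rep(log$metadata$session_index, n),
    task = vapply(trials, function(tr) tr$task, character(1)),
    trial_index = vapply(trials, function(tr) tr$trial_index, integer(1)),
    forced = as.integer(vapply(trials, function(tr) tr$forced, logical(1))),
    outcome = vapply(trials, function(tr) tr$outcome, character(1)),
    rewarded = as.integer(vapply(trials, function(tr) tr$rewarded, logical(1))),
    onset_s = round_ms(get(function(tr) tr$onset_s)),
    end_s = round_ms(get(function(tr) tr$end_s)),
    response_latency_s = round_ms(get(function(tr)
      if (is.na(tr$response_latency_s)) NA_real_ else tr$response_latency_s)),
    n_touches = vapply(trials, function(tr) length(tr$touches), integer(1)),
    dot1_x = dot_field(1L, function(s) s$center_x_px, NA_real_),
    dot1_y = dot_field(1L, function(s) s$center_y_px, NA_real_),
    dot1_diam = dot_field(1L, function(s) s$diameter_px, NA_real_),
    dot1_label = dot_field(1L, function(s) s$label, NA_character_),
    dot2_x = dot_field(2L, function(s) s$center_x_px, NA_real_),
    dot2_y = dot_field(2L, function(s) s$center_y_px, NA_real_),
    dot2_diam = dot_field(2L, function(s) s$diameter_px, NA_real_),
    dot2_label = dot_field(2L, function(s) s$label, NA_character_),
    first_touch_x = round_ms(first_touch(function(t) t$x_px)),
    first_touch_y = round_ms(first_touch(function(t) t$y_px)),
    stringsAsFactors = FALSE
  )
}

format_num <- function(x) ifelse(is.na(x), "", formatC(x, format = "fg",
                                                       digits = 15))

#' Write a trial log as CSV
#'
#' Writes the flattened record table (header + one row per trial). The
#' write/read pair is an identity on records.
#'
#' @param log A `dot_session_log`, or a record data frame with the columns
#'   of [trial_log_columns()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  rec <- if (inherits(log, "dot_session_log")) session_log_records(log) else log
  if (!identical(names(rec), trial_log_columns()))
    dt_spec_error("record columns do not match trial_log_columns()")
  out <- rec
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- format_num(out[[nm]])
    else out[[nm]][is.na(out[[nm]])] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

trial_log_colclasses <- function() {
  cls <- c(group_id = "character", session_index = "integer",
           task = "character", trial_index = "integer", forced = "integer",
           outcome = "character", rewarded = "integer", onset_s = "numeric",
           end_s = "numeric", response_latency_s = "numeric",
           n_touches = "integer", dot1_x = "numeric", dot1_y = "numeric",
           dot1_diam = "numeric", dot1_label = "character",
           dot2_x = "numeric", dot2_y = "numeric", dot2_diam = "numeric",
           dot2_label = "character", first_touch_x = "numeric",
           first_touch_y = "numeric")
  stopifnot(identical(names(cls), trial_log_columns()))
  cls
}

#' Read and validate a trial-log CSV
#'
#' Parses a file written by [write_trial_log()] and validates every row
#' against the trial invariants (reward iff correct, forced implies
#' correct, `end_s >= onset_s`, non-negative latency, counts consistent).
#' Validation failures name the offending line and field.
#'
#' @param path CSV file path.
#' @return Record data frame (columns of [trial_log_columns()]).
#' @export
read_trial_log <- function(path) {
  header <- utils::read.csv(path, nrows = 1, header = FALSE,
                            colClasses = "character")
  if (!identical(unname(unlist(header)), trial_log_columns()))
    dt_parse_error(sprintf("%s line 1: bad header (expected %s)",
                           path, paste(trial_log_columns(), collapse = ",")))
  rec <- tryCatch(
    utils::read.csv(path, colClasses = trial_log_colclasses(),
                    na.strings = ""),
    error = function(e) dt_parse_error(sprintf("%s: %s", path, conditionMessage(e)))
  )
  rec$group_id[is.na(rec$group_id)] <- ""
  validate_trial_records(rec, path)
  rec
}

validate_trial_records <- function(rec, path = "<records>") {
  fail <- function(row, field, why)
    dt_parse_error(sprintf("%s line %d: field '%s' %s", path, row + 1L,
                           field, why), row = row, field = field)
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    if (!r$task %in% TASKS) fail(i, "task", "is not a known task")
    if (!r$outcome %in% c("correct", "incorrect", "aborted"))
      fail(i, "outcome", "is not a valid outcome")
    if (!r$forced %in% c(0L, 1L)) fail(i, "forced", "must be 0/1")
    if (!r$rewarded %in% c(0L, 1L)) fail(i, "rewarded", "must be 0/1")
    if ((r$rewarded == 1L) != (r$outcome == "correct"))
      fail(i, "rewarded", "must be 1 exactly for correct outcomes")
    if (r$forced == 1L && r$outcome != "correct")
      fail(i, "forced", "trials must have a correct outcome")
    if (r$forced == 1L && r$task != "two_number_dot")
      fail(i, "forced", "is only valid for two_number_dot")
    if (is.na(r$onset_s) || is.na(r$end_s) || r$end_s < r$onset_s)
      fail(i, "end_s", "must be >= onset_s")
    if (!is.na(r$response_latency_s) && r$response_latency_s < 0)
      fail(i, "response_latency_s", "must be >= 0")
    if (r$n_touches == 0L && !is.na(r$response_latency_s))
      fail(i, "response_latency_s", "must be empty when n_touches = 0")
    if (r$n_touches > 0L && is.na(r$response_latency_s))
      fail(i, "response_latency_s", "must be present when touches occurred")
  }
  invisible(rec)
}

#' Write feedback events as JSONL
#'
#' One JSON object per line with keys `kind`, `time_s`, `session_index`.
#'
#' @param events List of feedback events (as in a `dot_session_log`), or a
#'   data frame with those three columns.
#' @param path Output file path.
#' @param session_index Session index stamped on each line (ignored when
#'   `events` is a data frame carrying its own).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, session_index = 1L) {
  df <- if (is.data.frame(events)) events else data.frame(
    kind = vapply(events, function(e) e$kind, character(1)),
    time_s = round_ms(vapply(events, function(e) e$time_s, numeric(1))),
    session_index = as.integer(session_index))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(list(kind = df$kind[i],
                                     time_s = df$time_s[i],
                                     session_index = df$session_index[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

EVENT_KINDS <- c("session_start_chime", "chime", "buzzer",
                 "led_green", "led_red", "led_blue", "pellet")

#' Read and validate a JSONL event log
#'
#' @param path JSONL file path.
#' @return Data frame with columns `kind`, `time_s`, `session_index`.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) dt_parse_error(
                      sprintf("%s line %d: invalid JSON", path, i)))
    for (k in c("kind", "time_s", "session_index"))
      if (is.null(obj[[k]]))
        dt_parse_error(sprintf("%s line %d: missing field '%s'", path, i, k))
    if (!obj$kind %in% EVENT_KINDS)
      dt_parse_error(sprintf("%s line %d: unknown event kind '%s'",
                             path, i, obj$kind))
    if (!is.numeric(obj$time_s) || obj$time_s < 0)
      dt_parse_error(sprintf("%s line %d: field 'time_s' must be >= 0", path, i))
    data.frame(kind = obj$kind, time_s = obj$time_s,
               session_index = as.integer(obj$session_index))
  })
  if (!length(rows))
    return(data.frame(kind = character(), time_s = numeric(),
                      session_index = integer()))
  do.call(rbind, rows)
}

#' Write session metadata sidecar
#' @param log A `dot_session_log`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_session_metadata <- function(log, path) {
  meta <- c(log$metadata,
            list(duration_s = log$spec$duration_s, iti_s = log$spec$iti_s,
                 seed = log$spec$seed, n_trials = length(log$trials)))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Persist a full session to a directory
#'
#' Writes `session_<idx>_trials.csv`, `session_<idx>_events.jsonl`, and
#' `session_<idx>_meta.json`.
#'
#' @param log A `dot_session_log`.
#' @param dir Output directory (created if absent).
#' @return The three file paths, invisibly.
#' @export
write_session <- function(log, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  i <- log$metadata$session_index
  paths <- file.path(dir, sprintf("session_%03d_%s", i,
                                  c("trials.csv", "events.jsonl", "meta.json")))
  write_trial_log(log, paths[1])
  write_event_log(log$events, paths[2], session_index = i)
  write_session_metadata(log, paths[3])
  invisible(paths)
}

#' Validate a directory of session logs
#'
#' Reads every trial CSV and event JSONL under `dir`, running all record
#' validations; returns the number of files checked.
#'
#' @param dir Directory containing files written by [write_session()].
#' @return Named integer vector `c(trial_logs =, event_logs =)`.
#' @export
validate_session_dir <- function(dir) {
  tf <- list.files(dir, pattern = "_trials\\.csv$", full.names = TRUE)
  ef <- list.files(dir, pattern = "_events\\.jsonl$", full.names = TRUE)
  for (f in tf) read_trial_log(f)
  for (f in ef) read_event_log(f)
  c(trial_logs = length(tf), event_logs = length(ef))
}
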