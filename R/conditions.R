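#' @keywords internal
dt_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dottask_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

dt_config_error    <- function(msg, ...) dt_error("dottask_config_error", msg, ...)
dt_placement_error <- function(msg, ...) dt_error("dottask_placement_error", msg, ...)
dt_spec_error      <- function(msg, ...) dt_error("dottask_spec_error", msg, ...)
dt_parse_error     <- function(msg, ...) dt_error("dottask_parse_error", msg, ...)

# scalar validation helpers used across constructors
check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    dt_spec_error(sprintf("`%s` must be a single non-missing number", name))
  if (strict_min && x <= min)
    dt_spec_error(sprintf("`%s` must be > %s", name, min))
  if (!strict_min && x < min)
    dt_spec_error(sprintf("`%s` must be >= %s", name, min))
  if (x > max)
    dt_spec_error(sprintf("`%s` must be <= %s", name, max))
  x
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, min = min)
  if (x != as.integer(x))
    dt_spec_error(sprintf("`%s` must be an integer", name))
  as.integer(x)
}
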