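# Classed conditions so callers (and the command-line wrapper) can
# distinguish bad input from degenerate geometry/statistics.

stop_input <- function(fmt, ...) {
  stop(errorCondition(
    sprintf(fmt, ...),
    class = c("relrbl_input_error", "relrbl_error", "error", "condition")
  ))
}

stop_degenerate <- function(fmt, ...) {
  stop(errorCondition(
    sprintf(fmt, ...),
    class = c("relrbl_degenerate_error", "relrbl_error", "error", "condition")
  ))
}

warn_relrbl <- function(fmt, ...) {
  warning(warningCondition(
    sprintf(fmt, ...),
    class = c("relrbl_warning", "warning", "condition")
  ))
}
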