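# Classed conditions so callers can distinguish bad input from bad data from
# numerical trouble. All inherit from "phygrow_error".

phygrow_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "phygrow_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_format     <- function(msg) phygrow_abort(msg, "phygrow_format_error")
stop_validation <- function(msg) phygrow_abort(msg, "phygrow_validation_error")
stop_domain     <- function(msg) phygrow_abort(msg, "phygrow_domain_error")
stop_lookup     <- function(msg) phygrow_abort(msg, "phygrow_lookup_error")
stop_degenerate <- function(msg) phygrow_abort(msg, "phygrow_degenerate_error")
stop_fit        <- function(msg) phygrow_abort(msg, "phygrow_fit_error")
stop_quality    <- function(msg) phygrow_abort(msg, "phygrow_quality_error")
stop_numeric    <- function(msg) phygrow_abort(msg, "phygrow_numeric_error")
stop_io         <- function(msg) phygrow_abort(msg, "phygrow_io_error")
stop_usage      <- function(msg) phygrow_abort(msg, "phygrow_usage_error")
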