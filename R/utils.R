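# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Report-style rounding (half-up on the absolute value), used for the
#' percent columns of the screening summaries.  Base `round()` rounds half
#' to even, which does not match conventional table formatting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Classed conditions so callers/tests can distinguish failure modes.
stop_asv <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "asvscreen_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_identifier <- function(msg) stop_asv(msg, "asvscreen_identifier_error")
stop_validation <- function(msg) stop_asv(msg, "asvscreen_validation_error")
stop_format     <- function(msg) stop_asv(msg, "asvscreen_format_error")
stop_metadata   <- function(msg) stop_asv(msg, "asvscreen_metadata_error")
stop_spec       <- function(msg) stop_asv(msg, "asvscreen_spec_error")
stop_data       <- function(msg) stop_asv(msg, "asvscreen_data_error")
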