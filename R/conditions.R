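# Structured error conditions so callers (and the CLI) can map failure
# categories to behaviour: argument errors, file-format errors, numerical /
# degenerate-geometry errors, and missing-column (key) errors.

abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "cryopick_error", "error"),
                      call = call))
}

abort_argument <- function(message, call = sys.call(-1)) {
  abort(message, "cryopick_argument_error", call)
}

abort_format <- function(message, call = sys.call(-1)) {
  abort(message, "cryopick_format_error", call)
}

abort_numerical <- function(message, call = sys.call(-1)) {
  abort(message, "cryopick_numerical_error", call)
}

abort_key <- function(message, call = sys.call(-1)) {
  abort(message, c("cryopick_key_error", "cryopick_argument_error"), call)
}
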