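# Classed conditions so callers (and the CLI) can map failures to exit codes.

anm_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "anm_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_parse <- function(msg) anm_abort(msg, "anm_parse_error")
abort_dimension <- function(msg) anm_abort(msg, "anm_dimension_error")
abort_argument <- function(msg) anm_abort(msg, "anm_argument_error")
abort_config <- function(msg) anm_abort(msg, "anm_config_error")
abort_degenerate <- function(msg) anm_abort(msg, "anm_degenerate_error")
abort_disconnected <- function(msg) anm_abort(msg, "anm_disconnected_error")

# Informational notices (model-reduction warnings, import diagnostics).
# message() so test runs stay quiet-able via suppressMessages().
anm_notify <- function(...) message("anmkit: ", ...)
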