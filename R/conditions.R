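# Classed conditions so callers (and the CLI) can map failures to exit codes
# without string-matching messages.

nr_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nr_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

nr_validation_error <- function(msg) nr_stop(msg, "nr_validation_error")
nr_format_error     <- function(msg) nr_stop(msg, "nr_format_error")
nr_domain_error     <- function(msg) nr_stop(msg, "nr_domain_error")
nr_degenerate_error <- function(msg) nr_stop(msg, "nr_degenerate_error")
nr_singular_error   <- function(msg) nr_stop(msg, "nr_singular_error")
nr_io_error         <- function(msg) nr_stop(msg, "nr_io_error")
nr_config_error     <- function(msg) nr_stop(msg, "nr_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
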