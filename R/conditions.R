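# Classed conditions so callers (and the CLI exit-code mapping) can tell
# user mistakes, bad data, and transport failures apart.

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("lazyse_usage_error", "lazyse_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("lazyse_data_error", "lazyse_error")))
}

stop_transport <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("lazyse_transport_error", "lazyse_error")))
}

stop_protocol <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("lazyse_protocol_error", "lazyse_error")))
}
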