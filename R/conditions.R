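# Classed conditions so callers (and the command-line driver) can map
# failure modes to exit codes without matching message text.
#   rpbivop_domain_error  - argument outside its mathematical domain
#   rpbivop_spec_error    - model specification / dimension mismatch
#   rpbivop_schema_error  - malformed input file or configuration
#   rpbivop_data_error    - degenerate data (empty category, collinearity)
#   rpbivop_usage_error   - function called outside its contract
stop_rpbivop <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "rpbivop_error", "error")))
}

stop_domain <- function(msg, ...) stop_rpbivop(msg, "rpbivop_domain_error", ...)
stop_spec   <- function(msg, ...) stop_rpbivop(msg, "rpbivop_spec_error", ...)
stop_schema <- function(msg, ...) stop_rpbivop(msg, "rpbivop_schema_error", ...)
stop_data   <- function(msg, ...) stop_rpbivop(msg, "rpbivop_data_error", ...)
stop_usage  <- function(msg, ...) stop_rpbivop(msg, "rpbivop_usage_error", ...)
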