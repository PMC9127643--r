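# Typed condition helpers. Every validation failure in the package raises a
# classed error so callers (and tests) can distinguish parse, format,
# integrity, configuration and domain problems.

sc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "speedcog_error", "error")))
}

sc_parse_error     <- function(msg) sc_abort(msg, "speedcog_parse_error")
sc_format_error    <- function(msg) sc_abort(msg, "speedcog_format_error")
sc_integrity_error <- function(msg) sc_abort(msg, "speedcog_integrity_error")
sc_config_error    <- function(msg) sc_abort(msg, "speedcog_config_error")
sc_domain_error    <- function(msg) sc_abort(msg, "speedcog_domain_error")

# scalar checks used throughout
is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x > 0
is_prob  <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
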