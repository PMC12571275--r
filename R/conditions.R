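# Classed conditions so callers (and the CLI exit-code contract) can
# distinguish capability errors from I/O, schema and validation failures.

ppiface_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ppiface_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

io_error         <- function(msg, ...) ppiface_error("ppiface_io_error", msg, ...)
schema_error     <- function(msg, ...) ppiface_error("ppiface_schema_error", msg, ...)
format_error     <- function(msg, ...) ppiface_error("ppiface_format_error", msg, ...)
validation_error <- function(msg, ...) ppiface_error("ppiface_validation_error", msg, ...)
capability_error <- function(msg, ...) ppiface_error("ppiface_capability_error", msg, ...)
lookup_error     <- function(msg, ...) ppiface_error("ppiface_lookup_error", msg, ...)
pattern_error    <- function(msg, ...) ppiface_error("ppiface_pattern_error", msg, ...)
generation_error <- function(msg, ...) ppiface_error("ppiface_generation_error", msg, ...)
empty_selection_error <- function(msg, ...) ppiface_error("ppiface_empty_selection", msg, ...)
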