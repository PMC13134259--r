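# Structured error conditions so callers (and the command wrappers) can
# distinguish validation, format, and degenerate-input failures.

abort_screlev <- function(message, class) {
  stop(structure(
    class = c(class, "screlev_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_validation <- function(message) abort_screlev(message, "screlev_validation_error")
abort_format     <- function(message) abort_screlev(message, "screlev_format_error")
abort_schema     <- function(message) abort_screlev(message, "screlev_schema_error")
abort_degenerate <- function(message) abort_screlev(message, "screlev_degenerate_error")
abort_contract   <- function(message) abort_screlev(message, "screlev_contract_error")
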