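# Typed error conditions. Every validation failure raises one of these classes
# so callers (and tests) can distinguish structural, value, format, coverage,
# domain and configuration problems.

abort_typed <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "surrofrax_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

format_error     <- function(msg, ...) abort_typed("surrofrax_format_error", msg, ...)
value_error      <- function(msg, ...) abort_typed("surrofrax_value_error", msg, ...)
structural_error <- function(msg, ...) abort_typed("surrofrax_structural_error", msg, ...)
domain_error     <- function(msg, ...) abort_typed("surrofrax_domain_error", msg, ...)
coverage_error   <- function(msg, ...) abort_typed("surrofrax_coverage_error", msg, ...)
config_error     <- function(msg, ...) abort_typed("surrofrax_config_error", msg, ...)
comparison_error <- function(msg, ...) abort_typed("surrofrax_comparison_error", msg, ...)
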