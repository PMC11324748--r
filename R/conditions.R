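# Classed conditions so callers (and the feature assembler) can react to
# specific failure modes instead of matching error strings.

pdssm_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "pdssm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

format_error <- function(msg, ...) pdssm_error("pdssm_format_error", msg, ...)
parse_error <- function(msg, ...) pdssm_error("pdssm_parse_error", msg, ...)
validation_error <- function(msg, ...) pdssm_error("pdssm_validation_error", msg, ...)
insufficient_data_error <- function(msg, ...) pdssm_error("pdssm_insufficient_data_error", msg, ...)
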