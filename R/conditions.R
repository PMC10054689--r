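# Structured error conditions so callers can distinguish annotation problems
# (bad references, degenerate polygons) from programming errors.

stop_gsm <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(paste0("gsm_", class), "gsm_error", "error", "condition")))
}
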