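# Classed error conditions so callers can distinguish failure modes
# programmatically (tryCatch on the subclass) rather than matching messages.

rdc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("rdcalign_", class), "rdcalign_error")))
}

rdc_assert <- function(cond, msg, class = "invalid_input") {
  if (!isTRUE(cond)) rdc_abort(msg, class)
  invisible(TRUE)
}
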