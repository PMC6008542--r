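# Classed conditions: every failure mode documented in the public API raises
# a condition whose class can be matched with tryCatch()/expect_error(),
# so callers never need to parse messages.

scc_abort <- function(class, message) {
  stop(errorCondition(message, class = c(class, "scclfp_error")))
}

scc_warn <- function(class, message) {
  warning(warningCondition(message, class = c(class, "scclfp_warning")))
}
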