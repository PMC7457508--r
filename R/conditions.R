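# Structured error conditions so callers (and the CLI) can distinguish
# programming errors, bad input files and genuinely non-isomorphic molecules.

abort_contract <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("symrmsd_contract_error", "symrmsd_error")))
}

abort_input <- function(msg) {
  stop(errorCondition(msg, class = c("symrmsd_input_error", "symrmsd_error")))
}

abort_not_isomorphic <- function(msg) {
  stop(errorCondition(msg, class = c("symrmsd_not_isomorphic", "symrmsd_error")))
}
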