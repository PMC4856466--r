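# Two error families so callers (and the command-line wrapper) can map
# configuration mistakes and malformed data to distinct exit codes.

stop_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg,
    class = c("paralogdose_config_error", "paralogdose_error")))
}

stop_data <- function(msg, call. = FALSE) {
  stop(errorCondition(msg,
    class = c("paralogdose_data_error", "paralogdose_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
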