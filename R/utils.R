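# Condition helpers: configuration errors (bad columns, bad parameters)
# vs data errors (unparseable content). The CLI maps these to exit codes.

configError <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("flexifdr_config_error", "error"),
                      call = call))
}

dataError <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("flexifdr_data_error", "error"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 17 significant digits round-trips an IEEE double exactly through text.
formatNumeric <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}
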