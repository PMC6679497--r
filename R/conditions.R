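# Structured conditions: every error/warning carries a machine-checkable
# class "synscreen_error_<code>" / "synscreen_warning_<code>" so callers and
# tests dispatch on codes, not message prose.

ss_stop <- function(code, message, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("synscreen_error_", code), "synscreen_error"),
    call = call
  ))
}

ss_warn <- function(code, message) {
  warning(warningCondition(
    message,
    class = c(paste0("synscreen_warning_", code), "synscreen_warning")
  ))
}

ss_info <- function(...) {
  message(sprintf(...))
}
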