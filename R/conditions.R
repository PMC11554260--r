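# Classed error conditions so callers and tests can match on class rather
# than on message text.
troph_error <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("troph_", class), "troph_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

troph_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("troph_", class), "troph_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}
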