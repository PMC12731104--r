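# Structured error conditions. Every user-facing failure is signalled with a
# condition class so callers (and the CLI) can dispatch on failure kind:
#   lpggnet_schema_error     - on-disk container / config file malformed
#   lpggnet_validation_error - inputs violate a documented precondition
#   lpggnet_numeric_error    - numerically degenerate computation

stop_lpggnet <- function(msg, class, data = list()) {
  cond <- errorCondition(msg, class = c(class, "lpggnet_error"), data = data)
  stop(cond)
}

stop_schema <- function(msg, data = list()) {
  stop_lpggnet(msg, "lpggnet_schema_error", data)
}

stop_validation <- function(msg, data = list()) {
  stop_lpggnet(msg, "lpggnet_validation_error", data)
}

stop_numeric <- function(msg, data = list()) {
  stop_lpggnet(msg, "lpggnet_numeric_error", data)
}

assert_that <- function(ok, msg, stopper = stop_validation) {
  if (!isTRUE(ok)) stopper(msg)
  invisible(TRUE)
}
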