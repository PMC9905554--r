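## Condition helpers: all package errors carry class "scsolub_error" plus a
## specific subclass ("schema_error", "validation_error", ...) so callers and
## tests can distinguish failure modes without matching message text.

stop_scsolub <- function(subclass, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("scsolub_", subclass), "scsolub_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## scalar numeric check
.chk_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_scsolub("validation_error", sprintf("'%s' must be a numeric scalar", name))
  }
  if (finite && !is.finite(x)) {
    stop_scsolub("validation_error", sprintf("'%s' must be finite", name))
  }
  if (positive && x <= 0) {
    stop_scsolub("validation_error", sprintf("'%s' must be > 0 (got %g)", name, x))
  }
  invisible(x)
}
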