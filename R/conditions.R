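# Classed conditions: every user-facing failure gets a herbipk_<class>
# condition so callers (and the pipeline driver) can branch on the class
# rather than on message text.

abort_pk <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(paste0("herbipk_", class), "herbipk_error")))
}

warn_pk <- function(class, message) {
  warning(warningCondition(message, class = c(paste0("herbipk_", class), "herbipk_warning")))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_pk("config", sprintf("'%s' must be a single finite number", name), field = name)
  if (positive && x <= 0)
    abort_pk("config", sprintf("'%s' must be > 0", name), field = name)
  invisible(x)
}
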