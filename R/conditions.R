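# Classed conditions so callers can distinguish failure modes.

clam_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("clam_", class), "clam_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

clam_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("clam_", class), "clam_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name, class = "invalid_geometry") {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    clam_abort(class, "`%s` must be finite and > 0 (got %s)", name,
               paste(format(x), collapse = ", "))
  }
  invisible(x)
}
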