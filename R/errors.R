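# Classed conditions so callers (and tests) can distinguish failure modes.
# Classes: vncsim_error_validation, _geometry, _config, _format, _fit,
# _degenerate, _report.

stop_validation <- function(msg, ...) {
  abort(msg, class = c("vncsim_error_validation", "vncsim_error"), ...)
}

stop_geometry <- function(msg, ...) {
  abort(msg, class = c("vncsim_error_geometry", "vncsim_error"), ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = c("vncsim_error_config", "vncsim_error"), ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = c("vncsim_error_format", "vncsim_error"), ...)
}

stop_fit <- function(msg, ...) {
  abort(msg, class = c("vncsim_error_fit", "vncsim_error"), ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = c("vncsim_error_degenerate", "vncsim_error"), ...)
}

stop_report <- function(msg, ...) {
  abort(msg, class = c("vncsim_error_report", "vncsim_error"), ...)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    stop_validation(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    stop_validation(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
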