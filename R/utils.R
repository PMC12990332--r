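# Classed conditions used across the package so callers can distinguish
# validation failures from format/schema problems programmatically.

ms_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "morphoscreen_error")))
}

ms_validation <- function(msg) ms_stop(msg, "morphoscreen_validation")
ms_format     <- function(msg) ms_stop(msg, "morphoscreen_format")
ms_schema     <- function(msg) ms_stop(msg, "morphoscreen_schema")
ms_io         <- function(msg) ms_stop(msg, "morphoscreen_io")

ms_warn <- function(msg) warning(warningCondition(msg, class = "morphoscreen_warning"))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
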