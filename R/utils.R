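#' Geometric mean
#'
#' @param x numeric vector of positive values.
#' @param na.rm drop missing values first.
#' @return The geometric mean as a single numeric value.
#' @keywords internal
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) stop("geometric mean of an empty vector")
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Structured warning with a machine-parseable code; the pipeline log keys on
# the code, interactive use sees the message.
zdose_warn <- function(code, message, call. = FALSE) {
  w <- structure(
    class = c("zdose_warning", "warning", "condition"),
    list(message = sprintf("[%s] %s", code, message), call = NULL, code = code)
  )
  warning(w)
  invisible(w)
}

zdose_stop <- function(code, message) {
  e <- structure(
    class = c("zdose_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, message), call = NULL, code = code)
  )
  stop(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
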