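`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
sq_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "spikequant_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Write a list as pretty JSON (scalars unboxed)
#' @noRd
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Sample standard deviation / mean, in percent
#' @noRd
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}
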