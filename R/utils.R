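`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
log_kv <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  kv <- list(...)
  parts <- vapply(seq_along(kv), function(i) {
    paste0(names(kv)[i], "=", format(kv[[i]], trim = TRUE))
  }, character(1))
  message(paste(c(paste0("stage=", stage), parts), collapse = " "))
  invisible(NULL)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
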