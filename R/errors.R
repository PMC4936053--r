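# Typed conditions and logging. Every validation error gets its own condition
# class ("guildomics_<what>") and carries the offending identifiers in the
# condition data, so callers can test for the failure mode rather than match
# message text.

g_abort <- function(msg, class, ...) {
  data <- list(...)
  if (length(data)) {
    ids <- vapply(data, function(x) paste(format(x), collapse = ","), "")
    msg <- paste0(msg, " [", paste(names(ids), ids, sep = "=", collapse = "; "), "]")
  }
  cond <- errorCondition(msg, class = c(paste0("guildomics_", class), "guildomics_error"))
  cond$data <- data
  stop(cond)
}

g_warn <- function(msg, class = "warning") {
  warning(warningCondition(msg, class = c(paste0("guildomics_", class), "guildomics_warning")))
}

#' Log a message to standard error
#'
#' All stochastic operations log their seed through this hook; set
#' `options(guildomics.verbose = FALSE)` to silence it.
#' @param ... message parts, concatenated.
#' @param level one of "INFO", "WARN", "DEBUG".
#' @return invisibly, the formatted line.
#' @export
g_log <- function(..., level = "INFO") {
  line <- paste0("[guildomics ", level, "] ", paste0(..., collapse = ""))
  if (isTRUE(getOption("guildomics.verbose", TRUE))) message(line)
  invisible(line)
}
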