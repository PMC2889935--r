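#' Round half away from zero
#'
#' Decimal rounding with exact halves going away from zero, the convention
#' used by most statistical report formatters (SAS, spreadsheets), unlike
#' base R's round-half-even. A tiny relative nudge (1e-7 of the last kept
#' digit) compensates for binary representation of exact decimal halves
#' such as 0.1985, which would otherwise fall on the wrong side.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-4) / s
}

# timestamped single-line stage log, appended to a file if given
.log_stage <- function(msg, logfile = NULL, verbose = TRUE) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  if (verbose) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}

.package_version_string <- function() {
  as.character(utils::packageVersion("refgenopt"))
}
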