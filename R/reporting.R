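#' Display rounding and formatting
#'
#' Reported statistics follow the field's table conventions: informativeness
#' statistics to 3 decimals, percentages to 1 decimal, both rounded half-up
#' (so 0.8285 prints as 0.829 and 15.38 as 15.4). Internal values are never
#' rounded; these helpers only affect display.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return `round_half_up` returns numeric; `fmt_stat`/`fmt_pct` return
#'   character.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @rdname round_half_up
#' @export
fmt_stat <- function(x, digits = 3) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' @rdname round_half_up
#' @export
fmt_pct <- function(x, digits = 1) {
  ifelse(is.nan(x), "NaN",
         formatC(round_half_up(x, digits), format = "f", digits = digits))
}

#' Write a data.frame as a deterministic TSV
#'
#' Plain tab-separated output with a header, no quoting and no row names:
#' identical input always produces byte-identical files.
#'
#' @param df data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report_tsv <- function(df, file) {
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}
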