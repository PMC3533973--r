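#' Classify a microsatellite repeat motif
#'
#' Parses the `"(CAG)12"` / `"(GGT)n"` motif grammar, with compound motifs
#' joined by dashes, e.g. `"(GA)7-(GA)8"`. A single repeat unit is classified
#' by its length (di- through hexa-nucleotide); motifs with more than one
#' unit are `"compound"`, and when every unit shares one length that common
#' unit length is reported alongside.
#'
#' @param motif motif string.
#' @return list with `repeat_class` (one of `"di"`, `"tri"`, `"tetra"`,
#'   `"penta"`, `"hexa"`, `"compound"`) and `unit_length` (integer; for a
#'   compound motif the shared unit length, or `NA` when units differ).
#' @export
classify_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1 || is.na(motif)) {
    stop("motif must be a single string")
  }
  units <- strsplit(trimws(motif), "-", fixed = TRUE)[[1]]
  pat <- "^\\(([ACGTacgt]+)\\)([0-9]+|n)$"
  ok <- grepl(pat, units)
  if (!length(units) || !all(ok)) {
    stop("unparseable repeat motif: ", dQuote(motif))
  }
  unit_len <- nchar(sub(pat, "\\1", units))
  classes <- c("2" = "di", "3" = "tri", "4" = "tetra", "5" = "penta", "6" = "hexa")
  if (any(!as.character(unit_len) %in% names(classes))) {
    stop("unsupported repeat unit length in motif: ", dQuote(motif))
  }
  if (length(units) > 1) {
    list(repeat_class = "compound",
         unit_length = if (length(unique(unit_len)) == 1) unit_len[1] else NA_integer_)
  } else {
    list(repeat_class = unname(classes[as.character(unit_len)]),
         unit_length = unit_len[1])
  }
}
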