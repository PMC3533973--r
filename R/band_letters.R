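#' Letter-code a family's bands at one locus
#'
#' Gel scoring shorthand for a maternal plant and its progeny at a single
#' locus: the maternal upper (larger) band is `"a"` and the lower band `"b"`
#' (a maternal homozygote is `"aa"`); bands not carried by the mother are
#' collected over all progeny and lettered `"c"`, `"d"`, ... in decreasing
#' molecular size, `"c"` for the largest. Each genotype is rendered with its
#' two letters in decreasing band size, e.g. `"ab"`, `"bc"` is rendered
#' `"cb"` when the non-maternal band is the larger one.
#'
#' The letter assignment depends only on the set of distinct non-maternal
#' sizes, so it is invariant to progeny order; equal sizes in different
#' individuals share one letter.
#'
#' @param mother allele labels of the mother at this locus: numeric (bp)
#'   vector of length 2 (homozygotes repeat the label).
#' @param progeny named list of progeny genotypes, each a numeric vector of
#'   length 0 (missing) or 2.
#' @return list with `mother` (its two-letter code), `progeny` (named
#'   character vector, `NA` for missing genotypes) and `letters` (named
#'   character vector mapping band size to letter).
#' @export
encode_band_letters <- function(mother, progeny) {
  mother <- as.numeric(mother)
  if (length(mother) != 2 || anyNA(mother)) {
    stop("mother genotype must be two numeric band sizes")
  }
  progeny <- lapply(progeny, as.numeric)
  lens <- lengths(progeny)
  if (any(!lens %in% c(0L, 2L))) {
    stop("each progeny genotype must have 0 or 2 allele labels")
  }
  m_sizes <- sort(unique(mother), decreasing = TRUE)
  letters_map <- if (length(m_sizes) == 2) {
    stats::setNames(c("a", "b"), m_sizes)
  } else {
    stats::setNames("a", m_sizes)
  }
  other <- sort(unique(setdiff(unlist(progeny), mother)), decreasing = TRUE)
  if (length(other) > 24) {
    stop("letter supply exhausted: ", length(other),
         " non-maternal band sizes but only letters c-z are available")
  }
  if (length(other)) {
    letters_map <- c(letters_map,
                     stats::setNames(letters[2 + seq_along(other)], other))
  }
  code <- function(g) {
    if (!length(g)) return(NA_character_)
    paste(letters_map[as.character(sort(g, decreasing = TRUE))], collapse = "")
  }
  list(mother = code(mother),
       progeny = vapply(progeny, code, character(1)),
       letters = letters_map)
}
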