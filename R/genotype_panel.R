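#' Construct a genotype panel
#'
#' A genotype panel bundles a marker table with individuals and their
#' codominant, disomic genotype calls. Allele calls are stored as a pair of
#' label matrices (individuals x loci); a label is usually a band size in
#' base pairs, but letter codes are accepted. A locus is either fully scored
#' (two allele copies; a single observed band is recorded as a homozygote
#' with multiplicity two) or missing (both labels `NA`).
#'
#' @param individuals data.frame with columns `id` (unique, character) and
#'   optionally `population`, `mother_id`, `father_id`.
#' @param markers data.frame with at least a column `id` (unique marker
#'   identifiers); typically the result of [read_marker_table()].
#' @param allele1,allele2 character matrices of allele labels, one row per
#'   individual and one column per marker, `NA` for missing. A cell must be
#'   missing in both matrices or in neither.
#' @param size_tolerance base pairs by which an integer allele label may fall
#'   outside its marker's declared size range before a warning is raised
#'   (violations are reported, never fatal). Default 0.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(individuals, markers, allele1, allele2,
                           size_tolerance = 0) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(individuals), "id" %in% names(markers))
  for (col in c("population", "mother_id", "father_id")) {
    if (!col %in% names(individuals)) {
      individuals[[col]] <- rep(NA_character_, nrow(individuals))
    }
  }
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id)) {
    stop("duplicated individual id: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  }
  if (anyDuplicated(markers$id)) {
    stop("duplicated marker id: ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  }
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "character"; storage.mode(allele2) <- "character"
  if (!identical(dim(allele1), dim(allele2))) {
    stop("allele1 and allele2 must have identical dimensions")
  }
  if (nrow(allele1) != nrow(individuals) || ncol(allele1) != nrow(markers)) {
    stop("allele matrices must be individuals x markers")
  }
  dimnames(allele1) <- dimnames(allele2) <- list(individuals$id, markers$id)
  if (any(is.na(allele1) != is.na(allele2))) {
    stop("half-missing genotype: each locus has 0 or 2 allele copies")
  }
  parents <- stats::na.omit(c(individuals$mother_id, individuals$father_id))
  orphan <- setdiff(parents, individuals$id)
  if (length(orphan)) {
    attr(individuals, "external_parents") <- orphan
  }
  panel <- structure(
    list(individuals = individuals, markers = markers,
         allele1 = allele1, allele2 = allele2),
    class = "genotype_panel")
  check_size_ranges(panel, tolerance = size_tolerance)
  panel
}

# warn (never fail) about integer allele labels outside a marker's declared
# size range; letter-coded labels are skipped
check_size_ranges <- function(panel, tolerance = 0) {
  m <- panel$markers
  if (!all(c("size_min_bp", "size_max_bp") %in% names(m))) return(invisible(NULL))
  bad <- character(0)
  for (j in seq_len(nrow(m))) {
    if (is.na(m$size_min_bp[j]) || is.na(m$size_max_bp[j])) next
    vals <- suppressWarnings(as.numeric(c(panel$allele1[, j], panel$allele2[, j])))
    vals <- vals[!is.na(vals)]
    out <- vals < m$size_min_bp[j] - tolerance | vals > m$size_max_bp[j] + tolerance
    if (any(out)) {
      bad <- c(bad, sprintf("%s: %s", m$id[j],
                            paste(unique(vals[out]), collapse = ",")))
    }
  }
  if (length(bad)) {
    warning("allele sizes outside declared marker range (tolerance ",
            tolerance, " bp): ", paste(bad, collapse = "; "), call. = FALSE)
  }
  invisible(bad)
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_missing <- sum(is.na(x$allele1))
  cat(sprintf("genotype_panel: %d individuals x %d loci (%d missing genotypes)\n",
              nrow(x$individuals), nrow(x$markers), n_missing))
  invisible(x)
}

#' Extract one locus genotype
#'
#' @param panel a [genotype_panel()].
#' @param individual_id,marker_id identifiers present in the panel.
#' @return Character vector of length 2 (allele labels; homozygotes repeat
#'   the label) or length 0 when the genotype is missing.
#' @export
locus_genotype <- function(panel, individual_id, marker_id) {
  if (!individual_id %in% rownames(panel$allele1)) {
    stop("unknown individual id: ", individual_id)
  }
  if (!marker_id %in% colnames(panel$allele1)) {
    stop("unknown marker id: ", marker_id)
  }
  a <- c(panel$allele1[individual_id, marker_id],
         panel$allele2[individual_id, marker_id])
  if (anyNA(a)) character(0) else a
}

#' Number of individuals / markers in a panel
#' @param panel a [genotype_panel()].
#' @return integer count.
#' @export
n_individuals <- function(panel) nrow(panel$individuals)

#' @rdname n_individuals
#' @export
n_markers <- function(panel) nrow(panel$markers)

#' Restrict a panel to a subset of loci
#'
#' @param panel a [genotype_panel()].
#' @param marker_ids marker identifiers to keep, in the requested order.
#' @return A `genotype_panel` over the selected loci.
#' @export
subset_loci <- function(panel, marker_ids) {
  missing <- setdiff(marker_ids, panel$markers$id)
  if (length(missing)) stop("unknown marker id: ", paste(missing, collapse = ", "))
  keep <- match(marker_ids, panel$markers$id)
  structure(
    list(individuals = panel$individuals,
         markers = panel$markers[keep, , drop = FALSE],
         allele1 = panel$allele1[, keep, drop = FALSE],
         allele2 = panel$allele2[, keep, drop = FALSE]),
    class = "genotype_panel")
}
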