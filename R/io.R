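#' Read a codominant genotype table
#'
#' Two tabular dialects are supported for individual x locus genotype calls:
#' \describe{
#'   \item{`two_col`}{two columns per locus, named `<locus>a` and `<locus>b`,
#'     one allele label each (the convention of common parentage software
#'     input files). A row with one filled and one blank cell at a locus is
#'     treated as missing, with a warning: an isolated single cell in this
#'     layout is more plausibly a data-entry gap than a homozygote.}
#'   \item{`slash`}{one column per locus holding `"161/189"`, `"161/161"`,
#'     or `""` for missing. A single value (`"161"`) is a homozygote scored
#'     from one band.}
#' }
#' Blank cells and `"0"` are missing. The field separator (tab or comma) is
#' sniffed from the header line. Reserved column names `id` (first column,
#' any name is accepted for it), `population`, `mother_id` and `father_id`
#' carry individual metadata.
#'
#' @param file path to a file, or a connection.
#' @param dialect `"two_col"` or `"slash"`.
#' @param text optional character scalar holding the table body instead of
#'   `file`.
#' @param markers optional marker table (see [read_marker_table()]) to attach;
#'   defaults to a minimal table built from the locus columns.
#' @param size_tolerance passed to [genotype_panel()].
#' @return A [genotype_panel()].
#' @export
read_genotype_table <- function(file, dialect = c("two_col", "slash"),
                                text = NULL, markers = NULL,
                                size_tolerance = 0) {
  dialect <- match.arg(dialect)
  raw <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else readLines(file)
  raw <- raw[nzchar(trimws(raw)) | seq_along(raw) == 1]
  if (!length(raw)) stop("empty genotype table")
  sep <- if (grepl("\t", raw[1], fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(text = raw, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "\"",
                           blank.lines.skip = FALSE)
  if (ncol(tab) < 1) stop("genotype table has no columns")
  meta_cols <- intersect(c("population", "mother_id", "father_id"), names(tab)[-1])
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated individual id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  locus_cols <- setdiff(names(tab)[-1], meta_cols)
  norm <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  n <- nrow(tab)
  if (dialect == "two_col") {
    if (length(locus_cols) %% 2 != 0) {
      stop("two_col dialect needs an even number of locus columns; trailing column: ",
           locus_cols[length(locus_cols)])
    }
    first <- locus_cols[seq(1, length(locus_cols), by = 2)]
    second <- locus_cols[seq(2, length(locus_cols), by = 2)]
    loci <- sub("a$", "", first)
    bad <- which(!(grepl("a$", first) & second == paste0(loci, "b")))
    if (length(bad)) {
      stop("unknown column structure in two_col dialect at column pair: ",
           first[bad[1]], " / ", second[bad[1]],
           " (expected <locus>a and <locus>b)")
    }
    a1 <- matrix(NA_character_, n, length(loci))
    a2 <- a1
    for (j in seq_along(loci)) {
      x <- norm(tab[[first[j]]]); y <- norm(tab[[second[j]]])
      half <- xor(is.na(x), is.na(y))
      if (any(half)) {
        warning(sprintf(
          "locus %s: %d genotype(s) with a single filled cell treated as missing (rows %s)",
          loci[j], sum(half), paste(which(half), collapse = ",")), call. = FALSE)
        x[half] <- NA_character_; y[half] <- NA_character_
      }
      a1[, j] <- x; a2[, j] <- y
    }
  } else {
    loci <- locus_cols
    a1 <- matrix(NA_character_, n, length(loci))
    a2 <- a1
    for (j in seq_along(loci)) {
      cells <- norm(tab[[loci[j]]])
      parts <- strsplit(ifelse(is.na(cells), "", cells), "/", fixed = TRUE)
      for (i in seq_len(n)) {
        p <- norm(parts[[i]])
        p <- p[!is.na(p)]
        if (length(p) == 0) next
        if (length(p) > 2) {
          stop(sprintf("locus %s, row %d: more than two alleles in %s",
                       loci[j], i, dQuote(cells[i])))
        }
        a1[i, j] <- p[1]
        a2[i, j] <- if (length(p) == 2) p[2] else p[1]
      }
    }
  }
  ind <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (col in meta_cols) ind[[col]] <- norm(tab[[col]])
  if (is.null(markers)) {
    markers <- data.frame(id = loci, stringsAsFactors = FALSE)
  } else {
    missing <- setdiff(loci, markers$id)
    if (length(missing)) {
      stop("loci absent from marker table: ", paste(missing, collapse = ", "))
    }
    markers <- markers[match(loci, markers$id), , drop = FALSE]
  }
  genotype_panel(ind, markers, a1, a2, size_tolerance = size_tolerance)
}

#' Write a genotype table
#'
#' Deterministic inverse of [read_genotype_table()]: markers and individuals
#' are emitted in panel order, missing genotypes as blank cells, homozygotes
#' in slash dialect as `"x/x"`. `read(write(panel))` reproduces the panel.
#'
#' @param panel a [genotype_panel()].
#' @param dialect `"two_col"` or `"slash"`.
#' @param file optional path; when given the text is also written there.
#' @param sep field separator, tab by default.
#' @return The table as a single character scalar, invisibly when `file` is
#'   given.
#' @export
write_genotype_table <- function(panel, dialect = c("two_col", "slash"),
                                 file = NULL, sep = "\t") {
  dialect <- match.arg(dialect)
  loci <- panel$markers$id
  ind <- panel$individuals
  meta_cols <- c("population", "mother_id", "father_id")
  meta_cols <- meta_cols[vapply(meta_cols, function(c) any(!is.na(ind[[c]])), logical(1))]
  blank <- function(x) ifelse(is.na(x), "", x)
  cols <- list(id = ind$id)
  for (col in meta_cols) cols[[col]] <- blank(ind[[col]])
  if (dialect == "two_col") {
    for (j in seq_along(loci)) {
      cols[[paste0(loci[j], "a")]] <- blank(panel$allele1[, j])
      cols[[paste0(loci[j], "b")]] <- blank(panel$allele2[, j])
    }
  } else {
    for (j in seq_along(loci)) {
      a <- panel$allele1[, j]; b <- panel$allele2[, j]
      cols[[loci[j]]] <- ifelse(is.na(a), "", paste0(a, "/", b))
    }
  }
  header <- paste(names(cols), collapse = sep)
  if (nrow(ind) == 0) {
    out <- paste0(header, "\n")
  } else {
    body <- do.call(paste, c(cols, sep = sep))
    out <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  }
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}

#' Read a marker metadata table
#'
#' Expects a TSV/CSV with the column layout of a duplex-panel marker table:
#' `set` (duplex set number), `ssr_id`, `type` (gSSR/eSSR), `motif`, `lg`,
#' `position_cm`, `n_alleles`, `size_range` (e.g. `"211-293"`), `d_min_bp`,
#' `pic`, `ne1p`, `primer_pmol`. Only `ssr_id` and `size_range` (or explicit
#' `size_min_bp`/`size_max_bp`) are required; all other columns are optional
#' metadata. The repeat class is derived from the motif when one is present.
#'
#' @param file path or connection; tab- or comma-separated with a header.
#' @return data.frame of markers (one row per locus) with columns `id`,
#'   `ssr_class`, `motif`, `repeat_class`, `linkage_group`, `lg_primary`,
#'   `position_cm`, `n_alleles`, `size_min_bp`, `size_max_bp`, `d_min_bp`,
#'   `pic`, `ne1p`, `duplex_set`, `primer_pmol` (absent metadata is `NA`).
#' @export
read_marker_table <- function(file) {
  first <- readLines(file, n = 1)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(file, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "\"")
  id_col <- intersect(c("ssr_id", "id", "marker_id"), names(tab))[1]
  if (is.na(id_col)) stop("marker table needs an ssr_id (or id) column")
  get <- function(col) if (col %in% names(tab)) trimws(tab[[col]]) else rep(NA_character_, nrow(tab))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c("", "NA"), NA, x)))
  out <- data.frame(
    id = trimws(tab[[id_col]]),
    ssr_class = get("type"),
    motif = get("motif"),
    linkage_group = gsub(" ", "", get("lg")),
    position_cm = num(get("position_cm")),
    n_alleles = num(get("n_alleles")),
    d_min_bp = num(get("d_min_bp")),
    pic = num(get("pic")),
    ne1p = num(get("ne1p")),
    duplex_set = num(get("set")),
    primer_pmol = num(get("primer_pmol")),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) {
    stop("duplicated marker id: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  if (all(c("size_min_bp", "size_max_bp") %in% names(tab))) {
    out$size_min_bp <- num(get("size_min_bp"))
    out$size_max_bp <- num(get("size_max_bp"))
  } else {
    rng <- get("size_range")
    mins <- maxs <- rep(NA_real_, nrow(tab))
    for (i in seq_len(nrow(tab))) {
      if (is.na(rng[i]) || rng[i] == "") next
      parts <- strsplit(rng[i], "-", fixed = TRUE)[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2 || anyNA(vals)) {
        stop(sprintf("malformed size range %s at row %d", dQuote(rng[i]), i))
      }
      mins[i] <- vals[1]; maxs[i] <- vals[2]
    }
    out$size_min_bp <- mins; out$size_max_bp <- maxs
  }
  bad <- which(!is.na(out$size_min_bp) & out$size_min_bp > out$size_max_bp)
  if (length(bad)) {
    stop("size_min_bp > size_max_bp at row ", paste(bad, collapse = ", "))
  }
  for (col in c("pic", "ne1p")) {
    v <- out[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop(col, " must lie in [0,1]")
  }
  out$lg_primary <- sub(",.*$", "", out$linkage_group)
  out$repeat_class <- vapply(out$motif, function(m) {
    if (is.na(m) || m == "") NA_character_ else classify_motif(m)$repeat_class
  }, character(1), USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Path to a packaged example data file
#'
#' @param name file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
duplexssr_example <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "duplexSSR")))
  }
  path <- system.file("extdata", name, package = "duplexSSR")
  if (path == "") stop("no packaged file named ", name)
  path
}
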