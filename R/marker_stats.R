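#' Allele frequencies at one locus
#'
#' Counts gene copies over the non-missing genotypes of a panel: each scored
#' individual contributes two copies (a homozygote contributes two of the
#' same label), missing genotypes are skipped.
#'
#' @param panel a [genotype_panel()].
#' @param marker_id locus to tabulate.
#' @return An `allele_freqs` object: list with `marker_id`, `freqs` (named
#'   numeric, relative frequencies summing to one, labels sorted) and
#'   `n_copies` (even gene-copy count).
#' @export
allele_frequencies <- function(panel, marker_id) {
  if (!marker_id %in% colnames(panel$allele1)) {
    stop("unknown marker id: ", marker_id)
  }
  labels <- c(panel$allele1[, marker_id], panel$allele2[, marker_id])
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("all genotypes missing at locus ", marker_id)
  counts <- table(labels)
  allele_freqs(as.numeric(counts) / sum(counts),
               labels = names(counts), marker_id = marker_id,
               n_copies = length(labels))
}

#' Construct an allele-frequency object directly
#'
#' @param p numeric vector of relative frequencies (all positive, summing
#'   to one within 1e-9).
#' @param labels allele labels; defaults to names of `p` or `1..k`.
#' @param marker_id locus identifier.
#' @param n_copies gene-copy count behind the estimate (even; 0 for
#'   population/theoretical frequencies).
#' @return An `allele_freqs` object.
#' @export
allele_freqs <- function(p, labels = NULL, marker_id = NA_character_,
                         n_copies = 0L) {
  p <- as.numeric(p)
  if (is.null(labels)) labels <- if (!is.null(names(p))) names(p) else as.character(seq_along(p))
  if (length(labels) != length(p)) stop("labels and p differ in length")
  if (any(p <= 0)) stop("every allele frequency must be > 0")
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies must sum to 1")
  ord <- order(labels)
  structure(list(marker_id = marker_id,
                 freqs = stats::setNames(p[ord], labels[ord]),
                 n_copies = as.integer(n_copies)),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("allele_freqs %s: %d alleles, %d gene copies\n",
              x$marker_id, length(x$freqs), x$n_copies))
  print(round(x$freqs, 4))
  invisible(x)
}

freq_vector <- function(freqs) {
  if (inherits(freqs, "allele_freqs")) freqs$freqs else as.numeric(freqs)
}

#' Expected heterozygosity
#'
#' Gene diversity \eqn{H_E = 1 - \sum_i p_i^2}. The unbiased (default) form
#' applies the small-sample correction \eqn{n/(n-1)} with \eqn{n} the
#' gene-copy count, the estimator reported by standard parentage software.
#'
#' @param freqs an [allele_freqs()] object (or bare frequency vector, in
#'   which case only the plain form is available).
#' @param unbiased apply the \eqn{n/(n-1)} correction (default `TRUE`).
#' @return Expected heterozygosity in `[0, 1]`.
#' @export
expected_heterozygosity <- function(freqs, unbiased = TRUE) {
  p <- freq_vector(freqs)
  h <- 1 - sum(p^2)
  if (!unbiased) return(h)
  n <- if (inherits(freqs, "allele_freqs")) freqs$n_copies else 0L
  if (n < 2) stop("unbiased expected heterozygosity needs n_copies >= 2")
  h * n / (n - 1)
}

#' Observed heterozygosity
#'
#' Fraction of scored (non-missing) individuals that carry two distinct
#' allele labels at the locus.
#'
#' @param panel a [genotype_panel()].
#' @param marker_id locus.
#' @return Observed heterozygosity in `[0, 1]`.
#' @export
observed_heterozygosity <- function(panel, marker_id) {
  if (!marker_id %in% colnames(panel$allele1)) {
    stop("unknown marker id: ", marker_id)
  }
  a <- panel$allele1[, marker_id]; b <- panel$allele2[, marker_id]
  keep <- !is.na(a)
  if (!any(keep)) stop("all genotypes missing at locus ", marker_id)
  mean(a[keep] != b[keep])
}

#' Polymorphic information content
#'
#' Botstein's PIC for a codominant locus:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}
#' computed via the power sums \eqn{a_2 = \sum p_i^2}, \eqn{a_4 = \sum p_i^4}
#' as \eqn{1 - a_2 - (a_2^2 - a_4)}.
#'
#' @param freqs an [allele_freqs()] object or frequency vector.
#' @return PIC in `[0, 1)`; 0 for a monomorphic locus.
#' @export
pic <- function(freqs) {
  p <- freq_vector(freqs)
  a2 <- sum(p^2); a4 <- sum(p^4)
  1 - a2 - (a2^2 - a4)
}

#' Single-parent non-exclusion probability (NE-1P)
#'
#' The probability that a random unrelated candidate cannot be excluded as
#' the sole parent of a random offspring at this locus, i.e. that candidate
#' and offspring share at least one allele, with both drawn under
#' Hardy-Weinberg equilibrium. The authoritative definition is the
#' exhaustive enumeration over offspring genotypes \eqn{g}:
#' \deqn{NE_{1P} = \sum_g P_{HWE}(g)\,[1 - P(\text{candidate carries neither allele of } g)]}
#' The default `"closed_form"` evaluates the equivalent Jamieson-Taylor
#' expression \eqn{1 - (1 - 4a_2 + 2a_2^2 + 4a_3 - 3a_4)} with power sums
#' \eqn{a_k = \sum_i p_i^k}; the two routes agree to numerical precision.
#'
#' @param freqs an [allele_freqs()] object or frequency vector.
#' @param method `"closed_form"` (default) or `"enumeration"`.
#' @return Non-exclusion probability in `(0, 1]`; 1 for a monomorphic locus.
#' @export
ne1p_locus <- function(freqs, method = c("closed_form", "enumeration")) {
  method <- match.arg(method)
  p <- freq_vector(freqs)
  if (method == "closed_form") {
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
    return(1 - (1 - 4 * a2 + 2 * a2^2 + 4 * a3 - 3 * a4))
  }
  k <- length(p)
  total <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      g_prob <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      miss <- if (i == j) (1 - p[i])^2 else (1 - p[i] - p[j])^2
      total <- total + g_prob * (1 - miss)
    }
  }
  total
}

#' Combine per-locus non-exclusion probabilities
#'
#' Multi-locus non-exclusion under linkage equilibrium is the product of the
#' per-locus values.
#'
#' @param locus_values numeric vector of per-locus probabilities in `(0, 1]`.
#' @return The product.
#' @export
ne1p_combined <- function(locus_values) {
  if (!length(locus_values)) stop("ne1p_combined needs at least one locus value")
  if (any(locus_values <= 0 | locus_values > 1)) {
    stop("per-locus non-exclusion probabilities must lie in (0, 1]")
  }
  prod(locus_values)
}

#' Per-locus summary statistics over a genotype panel
#'
#' Computes, for every locus, the allele count, observed and expected
#' heterozygosity, PIC and NE-1P from the panel's genotypes, and attaches a
#' mean/min/max aggregate over loci. Values are exact; use [fmt_stat()] for
#' the conventional 3-decimal display.
#'
#' @param panel a [genotype_panel()] with at least one marker.
#' @param unbiased use the unbiased expected-heterozygosity estimator.
#' @return data.frame with one row per marker (`marker_id`, `k_alleles`,
#'   `h_obs`, `h_exp`, `pic`, `ne1p`) and an `"aggregate"` attribute holding
#'   mean/min/max of each statistic.
#' @export
summarize_markers <- function(panel, unbiased = TRUE) {
  if (n_markers(panel) < 1) stop("panel has no markers")
  rows <- lapply(panel$markers$id, function(m) {
    f <- allele_frequencies(panel, m)
    data.frame(marker_id = m,
               k_alleles = length(f$freqs),
               h_obs = observed_heterozygosity(panel, m),
               h_exp = expected_heterozygosity(f, unbiased = unbiased),
               pic = pic(f),
               ne1p = ne1p_locus(f),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "aggregate") <- stat_aggregate(out[c("k_alleles", "h_obs", "h_exp", "pic", "ne1p")])
  out
}

#' Aggregate cached statistics of a marker metadata table
#'
#' Mean/min/max over the `pic` and `ne1p` columns of a marker table (such as
#' a published duplex-panel table), without needing genotypes.
#'
#' @param markers data.frame from [read_marker_table()].
#' @return data.frame with rows `mean`, `min`, `max` and one column per
#'   available statistic.
#' @export
marker_table_stats <- function(markers) {
  cols <- intersect(c("n_alleles", "pic", "ne1p"), names(markers))
  cols <- cols[vapply(cols, function(c) any(!is.na(markers[[c]])), logical(1))]
  if (!length(cols)) stop("marker table carries no pic/ne1p/n_alleles values")
  stat_aggregate(markers[cols])
}

stat_aggregate <- function(df) {
  agg <- vapply(df, function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), min = min(v), max = max(v))
  }, numeric(3))
  as.data.frame(agg)
}
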