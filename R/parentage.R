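#' Maternal-compatibility status of a progeny genotype at one locus
#'
#' Compares progeny allele labels with the maternal genotype at the same
#' locus:
#' \describe{
#'   \item{`maternal_subset`}{every progeny allele occurs in the mother
#'     (consistent with selfing; either maternal homozygote qualifies).}
#'   \item{`nonmaternal_present`}{at least one maternal and at least one
#'     non-maternal allele (a pollen allele from another plant).}
#'   \item{`no_maternal_allele`}{no allele shared with the mother.}
#'   \item{`missing`}{either genotype unscored.}
#' }
#'
#' @param mother,progeny allele-label vectors of length 0 (missing) or 2.
#' @return One of the four status strings.
#' @export
locus_status <- function(mother, progeny) {
  if (!length(mother) || !length(progeny) || anyNA(mother) || anyNA(progeny)) {
    return("missing")
  }
  shared <- progeny %in% mother
  if (all(shared)) "maternal_subset"
  else if (!any(shared)) "no_maternal_allele"
  else "nonmaternal_present"
}

#' Classify progeny as selfed, outcrossed or contaminant
#'
#' Applies the maternal-allele rules locus by locus, then combines:
#' a progeny with no maternal allele at `contaminant_min_loci` or more loci
#' is a seed `contaminant`; otherwise a progeny carrying any non-maternal
#' allele is `outcrossed` (a hybrid); a progeny whose alleles are a subset of
#' the maternal genotype at every scored locus is `selfed`. Progeny scored at
#' fewer than `min_scored` loci are `undetermined` (missing loci are never
#' evidence). With `strict_single_mismatch = FALSE`, loci sharing no
#' maternal allele but too few to call a contaminant are not treated as
#' outcross evidence; a progeny whose only discordance is such loci is then
#' left `undetermined` rather than called outcrossed.
#'
#' When `father_id` is given (a known pollen donor, as in a two-parent
#' crossing design), the same maternal rules decide selfed vs hybrid; the
#' paternal genotype only annotates hybrid loci, via the count of loci whose
#' non-maternal alleles are all present in the father.
#'
#' @param panel a [genotype_panel()].
#' @param mother_id individual id of the maternal parent.
#' @param progeny_ids individual ids to classify.
#' @param loci marker ids to use (default: every panel marker).
#' @param contaminant_min_loci minimum count of loci with no maternal allele
#'   for a contaminant call (default 2).
#' @param min_scored minimum number of non-missing loci for any call
#'   (default 1).
#' @param strict_single_mismatch treat below-threshold `no_maternal_allele`
#'   loci as outcross evidence (default `TRUE`).
#' @param father_id optional pollen-donor id, annotation only.
#' @return data.frame with one row per progeny: `progeny_id`, `mother_id`,
#'   `n_scored`, `n_maternal_subset`, `n_nonmaternal`, `n_no_maternal`,
#'   `overall` (selfed / outcrossed / contaminant / undetermined) and, when
#'   `father_id` is given, `n_paternal_consistent`. The per-locus status
#'   matrix is attached as attribute `"statuses"`.
#' @export
classify_progeny <- function(panel, mother_id, progeny_ids, loci = NULL,
                             contaminant_min_loci = 2L, min_scored = 1L,
                             strict_single_mismatch = TRUE,
                             father_id = NULL) {
  if (is.null(loci)) loci <- panel$markers$id
  unknown <- setdiff(c(mother_id, progeny_ids, father_id),
                     panel$individuals$id)
  if (length(unknown)) {
    stop("unknown individual id: ", paste(unknown, collapse = ", "))
  }
  if (!length(progeny_ids)) stop("no progeny to classify")
  bad_loci <- setdiff(loci, panel$markers$id)
  if (length(bad_loci)) stop("unknown marker id: ", paste(bad_loci, collapse = ", "))

  a1 <- panel$allele1[progeny_ids, loci, drop = FALSE]
  a2 <- panel$allele2[progeny_ids, loci, drop = FALSE]
  statuses <- matrix("missing", length(progeny_ids), length(loci),
                     dimnames = list(progeny_ids, loci))
  pat_consistent <- matrix(FALSE, length(progeny_ids), length(loci))
  for (j in seq_along(loci)) {
    mo <- locus_genotype(panel, mother_id, loci[j])
    if (!length(mo)) next
    x <- a1[, j]; y <- a2[, j]
    scored <- !is.na(x)
    in1 <- x %in% mo; in2 <- y %in% mo
    st <- ifelse(in1 & in2, "maternal_subset",
                 ifelse(!in1 & !in2, "no_maternal_allele", "nonmaternal_present"))
    statuses[scored, j] <- st[scored]
    if (!is.null(father_id)) {
      fa <- locus_genotype(panel, father_id, loci[j])
      if (length(fa)) {
        ok1 <- in1 | (x %in% fa); ok2 <- in2 | (y %in% fa)
        pat_consistent[, j] <- scored & st != "maternal_subset" & ok1 & ok2
      }
    }
  }
  n_scored <- rowSums(statuses != "missing")
  n_sub <- rowSums(statuses == "maternal_subset")
  n_non <- rowSums(statuses == "nonmaternal_present")
  n_nomat <- rowSums(statuses == "no_maternal_allele")

  if (any(n_scored == 0)) {
    warning("progeny sharing no scored locus with the mother left undetermined: ",
            paste(progeny_ids[n_scored == 0], collapse = ", "), call. = FALSE)
  }
  overall <- rep("undetermined", length(progeny_ids))
  is_cont <- n_nomat >= contaminant_min_loci
  enough <- n_scored >= max(1L, min_scored)
  outcross_evidence <- n_non > 0 |
    (strict_single_mismatch & n_nomat > 0)
  overall[is_cont] <- "contaminant"
  overall[!is_cont & enough & outcross_evidence] <- "outcrossed"
  overall[!is_cont & enough & !outcross_evidence & n_nomat == 0] <- "selfed"

  out <- data.frame(progeny_id = progeny_ids, mother_id = mother_id,
                    n_scored = n_scored, n_maternal_subset = n_sub,
                    n_nonmaternal = n_non, n_no_maternal = n_nomat,
                    overall = overall, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(father_id)) out$n_paternal_consistent <- rowSums(pat_consistent)
  attr(out, "statuses") <- statuses
  class(out) <- c("progeny_calls", "data.frame")
  out
}

#' Selfing-ratio percentage
#'
#' `100 * n_selfed / (n_selfed + n_outcrossed)`; contaminants (and
#' undetermined progeny) are excluded from the denominator. `NaN` when no
#' progeny could be assigned either class.
#'
#' @param n_selfed,n_outcrossed counts.
#' @return Percentage (0-100), or `NaN` for an empty denominator.
#' @export
selfing_ratio_pct <- function(n_selfed, n_outcrossed) {
  denom <- n_selfed + n_outcrossed
  if (denom == 0) return(NaN)
  100 * n_selfed / denom
}

#' Aggregate progeny calls into a selfing estimate
#'
#' @param calls a [classify_progeny()] result (or any data.frame with
#'   `progeny_id` and `overall` columns).
#' @param family_of optional named character vector mapping progeny id to
#'   family id, for a per-family breakdown.
#' @return A `selfing_estimate`: list with the four class counts,
#'   `ratio_pct`, `contaminant_pct` (share of all calls) and, when families
#'   are given, a `per_family` data.frame.
#' @export
selfing_estimate <- function(calls, family_of = NULL) {
  if (!nrow(calls)) stop("no progeny calls to aggregate")
  count <- function(df) {
    c(n_selfed = sum(df$overall == "selfed"),
      n_outcrossed = sum(df$overall == "outcrossed"),
      n_contaminant = sum(df$overall == "contaminant"),
      n_undetermined = sum(df$overall == "undetermined"))
  }
  n <- count(calls)
  out <- list(n_selfed = n[["n_selfed"]], n_outcrossed = n[["n_outcrossed"]],
              n_contaminant = n[["n_contaminant"]],
              n_undetermined = n[["n_undetermined"]],
              ratio_pct = selfing_ratio_pct(n[["n_selfed"]], n[["n_outcrossed"]]),
              contaminant_pct = 100 * n[["n_contaminant"]] / nrow(calls))
  if (!is.null(family_of)) {
    fam <- family_of[calls$progeny_id]
    if (anyNA(fam)) stop("family_of lacks an entry for some progeny")
    per <- lapply(split(seq_len(nrow(calls)), fam), function(i) {
      as.data.frame(as.list(count(calls[i, , drop = FALSE])))
    })
    per_family <- do.call(rbind, per)
    per_family <- cbind(family = names(per), per_family)
    rownames(per_family) <- NULL
    per_family$family_size <- rowSums(per_family[-1])
    out$per_family <- per_family
  }
  structure(out, class = "selfing_estimate")
}

#' @export
print.selfing_estimate <- function(x, ...) {
  cat(sprintf("selfed %d, outcrossed %d, contaminant %d, undetermined %d\n",
              x$n_selfed, x$n_outcrossed, x$n_contaminant, x$n_undetermined))
  cat(sprintf("selfing ratio (contaminants excluded): %s%%\n", fmt_pct(x$ratio_pct)))
  cat(sprintf("contaminant fraction of all progeny: %s%%\n", fmt_pct(x$contaminant_pct)))
  invisible(x)
}

#' Selfing estimate from a family-outcome table
#'
#' Aggregates a per-family outcome table (columns `family`, `n_selfed`,
#' `n_outcrossed`, `n_contaminant`, optionally `family_size`) into totals,
#' the overall selfing ratio and the contaminant fraction.
#'
#' @param families data.frame in the layout above.
#' @return A `selfing_estimate` with a `per_family` element echoing the
#'   input.
#' @export
family_table_estimate <- function(families) {
  need <- c("family", "n_selfed", "n_outcrossed", "n_contaminant")
  if (!all(need %in% names(families))) {
    stop("family table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"family_size" %in% names(families)) {
    families$family_size <- families$n_selfed + families$n_outcrossed +
      families$n_contaminant
  }
  mism <- families$family_size !=
    families$n_selfed + families$n_outcrossed + families$n_contaminant
  if (any(mism)) {
    stop("family_size does not equal the class counts for family: ",
         paste(families$family[mism], collapse = ", "))
  }
  ns <- sum(families$n_selfed); no <- sum(families$n_outcrossed)
  nc <- sum(families$n_contaminant); ntot <- sum(families$family_size)
  structure(list(n_selfed = ns, n_outcrossed = no, n_contaminant = nc,
                 n_undetermined = 0L,
                 ratio_pct = selfing_ratio_pct(ns, no),
                 contaminant_pct = 100 * nc / ntot,
                 per_family = families),
            class = "selfing_estimate")
}

#' Cumulative selfing ratio with increasing numbers of loci
#'
#' For each requested subset size `k`, draws `n_reps` random loci subsets
#' (without replacement within a subset; with `one_per_lg`, loci are drawn
#' on `k` distinct linkage groups, mirroring random selection of unlinked
#' duplex loci), classifies the progeny using only those loci, and records
#' the selfing ratio. The mean over replicates traces how apparent selfing
#' declines as more informative loci are added; the standard error
#' quantifies subset-to-subset spread.
#'
#' @inheritParams classify_progeny
#' @param k_values subset sizes to evaluate.
#' @param n_reps random subsets per `k` (default 100).
#' @param one_per_lg draw at most one locus per linkage group (default
#'   `TRUE`; requires an `lg_primary` or `linkage_group` column in the
#'   panel's marker table).
#' @param seed integer seed; the draw sequence is fully reproducible.
#' @param ... passed to [classify_progeny()] (classification policy knobs).
#' @return data.frame with columns `k`, `mean_ratio_pct`, `se_ratio_pct`,
#'   `n_reps`; the replicate-level ratios are attached as attribute
#'   `"replicates"` (a list of numeric vectors, one per `k`).
#' @export
cumulative_selfing_curve <- function(panel, mother_id, progeny_ids, k_values,
                                     n_reps = 100L, one_per_lg = TRUE,
                                     seed, ...) {
  loci <- panel$markers$id
  lg <- if ("lg_primary" %in% names(panel$markers)) {
    panel$markers$lg_primary
  } else if ("linkage_group" %in% names(panel$markers)) {
    sub(",.*$", "", panel$markers$linkage_group)
  } else if (one_per_lg) {
    stop("one_per_lg needs linkage-group metadata in the marker table")
  }
  n_avail <- if (one_per_lg) length(unique(lg)) else length(loci)
  if (any(k_values > n_avail)) {
    stop("k exceeds the ", n_avail, " available ",
         if (one_per_lg) "linkage groups" else "loci")
  }
  if (missing(seed)) stop("a seed is required for the random loci subsets")
  with_seed(seed, {
    reps <- lapply(k_values, function(k) {
      vapply(seq_len(n_reps), function(r) {
        chosen <- if (one_per_lg) {
          groups <- sample(unique(lg), k)
          vapply(groups, function(g) {
            cand <- loci[lg == g]
            if (length(cand) == 1) cand else sample(cand, 1)
          }, character(1))
        } else {
          sample(loci, k)
        }
        calls <- classify_progeny(panel, mother_id, progeny_ids,
                                  loci = chosen, ...)
        est <- selfing_estimate(calls)
        est$ratio_pct
      }, numeric(1))
    })
  })
  out <- data.frame(
    k = k_values,
    mean_ratio_pct = vapply(reps, function(r) mean(r, na.rm = TRUE), numeric(1)),
    se_ratio_pct = vapply(reps, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 2) 0 else stats::sd(r) / sqrt(length(r))
    }, numeric(1)),
    n_reps = n_reps)
  attr(out, "replicates") <- reps
  out
}

#' Probability that an outcross escapes detection
#'
#' An outcrossed offspring always carries one maternal gamete, so it is
#' (mis)classified as selfed exactly when its pollen allele is itself one of
#' the maternal alleles at every scored locus. Under linkage equilibrium
#' that probability is the product over loci of the pollen-pool frequency
#' mass on the maternal alleles.
#'
#' @param mother_genotypes named list (by locus) of maternal allele pairs.
#' @param pollen_freqs named list (by locus) of [allele_freqs()] for the
#'   pollen pool.
#' @param loci loci to include (default: all in `mother_genotypes`).
#' @return Probability in `[0, 1]`.
#' @export
expected_undetected_outcross <- function(mother_genotypes, pollen_freqs,
                                         loci = names(mother_genotypes)) {
  missing_m <- setdiff(loci, names(mother_genotypes))
  missing_p <- setdiff(loci, names(pollen_freqs))
  if (length(missing_m) || length(missing_p)) {
    stop("locus absent from ",
         if (length(missing_m)) "mother genotypes: " else "pollen frequencies: ",
         paste(c(missing_m, missing_p), collapse = ", "))
  }
  per_locus <- vapply(loci, function(l) {
    f <- pollen_freqs[[l]]
    p <- if (inherits(f, "allele_freqs")) f$freqs else f
    sum(p[names(p) %in% as.character(mother_genotypes[[l]])])
  }, numeric(1))
  prod(per_locus)
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
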