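#' Configuration for a synthetic progeny population
#'
#' Describes a simulated mating design with known truth: maternal plants
#' drawn from a Hardy-Weinberg population, progeny that are selfed (two
#' independent maternal gametes), outcrossed (one maternal gamete plus one
#' pollen-pool gamete) or seed contaminants (a full Hardy-Weinberg draw
#' unrelated to the listed mother), and optional missing-data noise. The
#' defaults emulate a single open-pollinated maternal plant genotyped at ten
#' unlinked microsatellite loci with eight alleles each — the typical
#' half-sib validation family in this line of work — with allele
#' frequencies drawn from a flat (concentration 1) Dirichlet.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus allele count per locus (scalar or per-locus
#'   vector).
#' @param freq_concentration symmetric Dirichlet concentration for allele
#'   frequencies (1 = flat; large values approach equifrequent alleles).
#' @param selfing_rate true probability that a non-contaminant progeny is
#'   selfed.
#' @param contamination_rate probability that a listed progeny is an
#'   unrelated seed contaminant.
#' @param n_progeny progeny per family.
#' @param n_families number of maternal families.
#' @param missing_rate per-genotype missing probability applied to progeny
#'   calls (mothers are always fully scored, as on a gel with duplicated
#'   parent lanes).
#' @param lg_assignment optional character vector (length `n_loci`) of
#'   linkage groups; defaults to one locus per group, matching the
#'   unlinked-loci design.
#' @param seed integer seed; a fixed seed makes the population byte-stable.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_loci = 10L, alleles_per_locus = 8L,
                              freq_concentration = 1, selfing_rate = 0,
                              contamination_rate = 0, n_progeny = 46L,
                              n_families = 1L, missing_rate = 0,
                              lg_assignment = NULL, seed = 1L) {
  stopifnot(n_loci >= 1, all(alleles_per_locus >= 1), freq_concentration > 0,
            selfing_rate >= 0, selfing_rate <= 1,
            contamination_rate >= 0, contamination_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            n_progeny >= 1, n_families >= 1)
  if (is.null(lg_assignment)) {
    lg_assignment <- sprintf("LG%02d", seq_len(n_loci))
  }
  if (length(lg_assignment) != n_loci) stop("lg_assignment must have one entry per locus")
  structure(list(n_loci = as.integer(n_loci),
                 alleles_per_locus = rep_len(as.integer(alleles_per_locus), n_loci),
                 freq_concentration = freq_concentration,
                 selfing_rate = selfing_rate,
                 contamination_rate = contamination_rate,
                 n_progeny = as.integer(n_progeny),
                 n_families = as.integer(n_families),
                 missing_rate = missing_rate,
                 lg_assignment = lg_assignment,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw per-locus allele frequencies
#'
#' Symmetric Dirichlet draws, one frequency vector per locus. Allele labels
#' are band-size-like integers (each locus gets its own size band) so the
#' simulated panels flow through the same scoring, letter-coding and
#' separation machinery as gel data.
#'
#' @inheritParams simulation_config
#' @param seed optional seed for a reproducible draw.
#' @return list of [allele_freqs()], one per locus, named `L01`, `L02`, ...
#' @export
simulate_frequencies <- function(n_loci, alleles_per_locus,
                                 freq_concentration = 1, seed = NULL) {
  stopifnot(n_loci >= 1, all(alleles_per_locus >= 1), freq_concentration > 0)
  k <- rep_len(as.integer(alleles_per_locus), n_loci)
  draw <- function() {
    lapply(seq_len(n_loci), function(l) {
      repeat {
        g <- stats::rgamma(k[l], shape = freq_concentration)
        if (sum(g) > 0 && all(g / sum(g) > 0)) break
      }
      labels <- 100L + 40L * (l - 1L) + 2L * (seq_len(k[l]) - 1L)
      allele_freqs(g / sum(g), labels = as.character(labels),
                   marker_id = sprintf("L%02d", l))
    })
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  names(out) <- sprintf("L%02d", seq_len(n_loci))
  out
}

#' Simulate a progeny population with known truth
#'
#' Implements the generative model in [simulation_config()]: pollen pool
#' and maternal source population share one Hardy-Weinberg frequency vector
#' per locus (panmixia). Mothers are drawn independently per family; each
#' progeny's true class is drawn i.i.d. with probabilities
#' `selfing_rate * (1 - contamination_rate)` (selfed),
#' `(1 - selfing_rate) * (1 - contamination_rate)` (outcrossed) and
#' `contamination_rate` (contaminant). Loci segregate independently.
#'
#' @param config a [simulation_config()].
#' @return list with `panel` (a [genotype_panel()] containing mothers and
#'   progeny, progeny carrying `mother_id`), `truth` (data.frame:
#'   `progeny_id`, `family`, `true_class`) and `pollen_freqs` (the
#'   generating [allele_freqs()] per locus).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    freqs <- simulate_frequencies(config$n_loci, config$alleles_per_locus,
                                  config$freq_concentration)
    loci <- names(freqs)
    gamete <- function(l) sample(names(freqs[[l]]$freqs), 1,
                                 prob = freqs[[l]]$freqs)
    n_fam <- config$n_families
    n_prog <- config$n_progeny
    mothers <- sprintf("F%02d", seq_len(n_fam))
    prog_ids <- unlist(lapply(seq_len(n_fam), function(f) {
      sprintf("F%02d-%03d", f, seq_len(n_prog))
    }))
    ids <- c(mothers, prog_ids)
    a1 <- matrix(NA_character_, length(ids), length(loci),
                 dimnames = list(ids, loci))
    a2 <- a1
    for (m in mothers) {
      for (l in loci) { a1[m, l] <- gamete(l); a2[m, l] <- gamete(l) }
    }
    class_probs <- c(selfed = config$selfing_rate * (1 - config$contamination_rate),
                     outcrossed = (1 - config$selfing_rate) * (1 - config$contamination_rate),
                     contaminant = config$contamination_rate)
    truth <- data.frame(progeny_id = prog_ids,
                        family = rep(mothers, each = n_prog),
                        true_class = NA_character_,
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(truth))) {
      cls <- sample(names(class_probs), 1, prob = class_probs)
      truth$true_class[r] <- cls
      pid <- truth$progeny_id[r]; mid <- truth$family[r]
      for (l in loci) {
        g <- switch(cls,
          selfed = sample(c(a1[mid, l], a2[mid, l]), 2, replace = TRUE),
          outcrossed = c(sample(c(a1[mid, l], a2[mid, l]), 1), gamete(l)),
          contaminant = c(gamete(l), gamete(l)))
        a1[pid, l] <- g[1]; a2[pid, l] <- g[2]
      }
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(prog_ids) * length(loci)) < config$missing_rate,
                     length(prog_ids), length(loci))
      a1[prog_ids, ][mask] <- NA_character_
      a2[prog_ids, ][mask] <- NA_character_
    }
    ind <- data.frame(id = ids,
                      population = "synthetic",
                      mother_id = c(rep(NA_character_, n_fam),
                                    rep(mothers, each = n_prog)),
                      father_id = NA_character_,
                      stringsAsFactors = FALSE)
    markers <- data.frame(id = loci,
                          linkage_group = config$lg_assignment,
                          lg_primary = config$lg_assignment,
                          position_cm = 50,
                          stringsAsFactors = FALSE)
    panel <- genotype_panel(ind, markers, a1, a2)
    list(panel = panel, truth = truth, pollen_freqs = freqs)
  })
}

#' Simulate, classify, and compare against the generating truth
#'
#' One full round trip of the pipeline on synthetic data: simulate a
#' population, classify every family's progeny against its mother, pool the
#' calls, and report the estimated selfing ratio beside the generating
#' selfing rate. Because an outcross whose pollen allele happens to be
#' maternal at every locus is indistinguishable from a selfed plant, the
#' estimate carries a predictable upward bias; the bias-corrected
#' expectation `100 * (s + (1 - s) * u)` — with `u` the
#' [expected_undetected_outcross()] probability averaged over mothers — is
#' returned alongside.
#'
#' @param config a [simulation_config()].
#' @param ... classification policy passed to [classify_progeny()].
#' @return list with `true_selfing_rate`, `estimated_ratio_pct`,
#'   `expected_ratio_pct` (bias-corrected expectation), `n_misclassified`
#'   (calls differing from truth), `estimate` (the pooled
#'   [selfing_estimate()]), `calls` and the generating `truth` table.
#' @export
recovery_experiment <- function(config, ...) {
  sim <- simulate_population(config)
  mothers <- sim$panel$individuals$id[is.na(sim$panel$individuals$mother_id)]
  all_calls <- lapply(mothers, function(m) {
    prog <- sim$truth$progeny_id[sim$truth$family == m]
    classify_progeny(sim$panel, m, prog, ...)
  })
  calls <- do.call(rbind, all_calls)
  est <- selfing_estimate(calls)
  u_per_mother <- vapply(mothers, function(m) {
    mg <- lapply(names(sim$pollen_freqs), function(l) locus_genotype(sim$panel, m, l))
    names(mg) <- names(sim$pollen_freqs)
    expected_undetected_outcross(mg, sim$pollen_freqs)
  }, numeric(1))
  s <- config$selfing_rate
  expected <- 100 * (s + (1 - s) * mean(u_per_mother))
  truth_map <- stats::setNames(sim$truth$true_class, sim$truth$progeny_id)
  list(true_selfing_rate = s,
       estimated_ratio_pct = est$ratio_pct,
       expected_ratio_pct = expected,
       n_misclassified = sum(calls$overall != truth_map[calls$progeny_id]),
       estimate = est,
       calls = calls,
       truth = sim$truth)
}
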