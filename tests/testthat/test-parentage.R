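test_that("per-locus maternal-compatibility statuses", {
  expect_equal(locus_status(c("a", "b"), c("b", "b")), "maternal_subset")
  expect_equal(locus_status(c("a", "b"), c("a", "c")), "nonmaternal_present")
  expect_equal(locus_status(c("a", "b"), c("c", "d")), "no_maternal_allele")
  expect_equal(locus_status(c("a", "b"), character(0)), "missing")
  expect_equal(locus_status(character(0), c("a", "b")), "missing")
})

make_family <- function(statuses_by_locus) {
  # build a panel realizing the requested per-locus status for one progeny
  n <- length(statuses_by_locus)
  loci <- sprintf("L%02d", seq_len(n))
  a1 <- matrix(NA_character_, 2, n); a2 <- a1
  for (j in seq_len(n)) {
    a1[1, j] <- "100"; a2[1, j] <- "110"
    g <- switch(statuses_by_locus[j],
                maternal_subset = c("100", "110"),
                nonmaternal_present = c("100", "300"),
                no_maternal_allele = c("300", "310"),
                missing = c(NA, NA))
    a1[2, j] <- g[1]; a2[2, j] <- g[2]
  }
  genotype_panel(data.frame(id = c("M", "P"), mother_id = c(NA, "M")),
                 data.frame(id = loci), a1, a2)
}

call_one <- function(statuses, ...) {
  p <- make_family(statuses)
  classify_progeny(p, "M", "P", ...)$overall
}

test_that("overall classification follows the maternal-allele rules", {
  expect_equal(call_one(rep("maternal_subset", 10)), "selfed")
  expect_equal(call_one(rep("no_maternal_allele", 6)), "contaminant")
  expect_equal(call_one(c("nonmaternal_present", rep("maternal_subset", 9))),
               "outcrossed")
  # the >= 2 loci contaminant threshold, exactly at the boundary
  expect_equal(call_one(c(rep("no_maternal_allele", 2), rep("maternal_subset", 8))),
               "contaminant")
  # one discordant locus below the threshold is outcross evidence by default
  expect_equal(call_one(c("no_maternal_allele", rep("maternal_subset", 9))),
               "outcrossed")
  # ... and inconclusive when strict_single_mismatch is off
  expect_equal(call_one(c("no_maternal_allele", rep("maternal_subset", 9)),
                        strict_single_mismatch = FALSE),
               "undetermined")
  # a raised threshold turns a 2-locus contaminant into an outcross call
  expect_equal(call_one(c(rep("no_maternal_allele", 2), rep("maternal_subset", 8)),
                        contaminant_min_loci = 3),
               "outcrossed")
})

test_that("missing loci are not evidence; unscored progeny are undetermined", {
  expect_equal(call_one(c("maternal_subset", "missing", "missing")), "selfed")
  expect_warning(out <- call_one(rep("missing", 4)), "no scored locus")
  expect_equal(out, "undetermined")
  expect_equal(call_one(c("maternal_subset", rep("missing", 3)), min_scored = 2),
               "undetermined")
  expect_error(classify_progeny(make_family("missing"), "M", "nobody"),
               "unknown individual id")
})

test_that("classification is invariant to locus and progeny order", {
  sim <- simulate_population(simulation_config(
    selfing_rate = 0.4, contamination_rate = 0.15, n_progeny = 40,
    missing_rate = 0.1, seed = 20))
  prog <- sim$truth$progeny_id
  loci <- sim$panel$markers$id
  base <- classify_progeny(sim$panel, "F01", prog)
  set.seed(1)
  shuf <- classify_progeny(sim$panel, "F01", sample(prog), loci = sample(loci))
  shuf <- shuf[match(prog, shuf$progeny_id), ]
  expect_equal(shuf$overall, base$overall)
  expect_equal(shuf$n_no_maternal, base$n_no_maternal)
})

test_that("adding loci never converts an outcross call to selfed", {
  sim <- simulate_population(simulation_config(
    selfing_rate = 0.3, n_progeny = 60, alleles_per_locus = 4, seed = 33))
  prog <- sim$truth$progeny_id
  loci <- sim$panel$markers$id
  sub <- classify_progeny(sim$panel, "F01", prog, loci = loci[1:4])$overall
  full <- classify_progeny(sim$panel, "F01", prog)$overall
  expect_false(any(sub == "outcrossed" & full == "selfed"))
})

test_that("known pollen donor annotates hybrid loci without changing calls", {
  ind <- data.frame(id = c("M", "D", "P1", "P2"),
                    mother_id = c(NA, NA, "M", "M"),
                    father_id = c(NA, NA, "D", "D"))
  markers <- data.frame(id = c("L1", "L2"))
  #       M        D        P1 (M x D)   P2 (foreign pollen at L2)
  a1 <- rbind(c("100", "110"), c("200", "210"), c("100", "110"), c("100", "110"))
  a2 <- rbind(c("102", "112"), c("202", "212"), c("200", "210"), c("200", "400"))
  p <- genotype_panel(ind, markers, a1, a2)
  calls <- classify_progeny(p, "M", c("P1", "P2"), father_id = "D")
  expect_equal(calls$overall, c("outcrossed", "outcrossed"))
  expect_equal(calls$n_paternal_consistent, c(2L, 1L))
})

test_that("selfing estimates use the contaminant-excluded denominator", {
  expect_equal(round_half_up(selfing_ratio_pct(10, 55), 1), 15.4)
  expect_equal(round_half_up(selfing_ratio_pct(34, 10), 1), 77.3)
  expect_true(is.nan(selfing_ratio_pct(0, 0)))
  calls <- data.frame(progeny_id = sprintf("p%d", 1:6),
                      overall = c("selfed", "outcrossed", "outcrossed",
                                  "contaminant", "contaminant", "undetermined"))
  est <- selfing_estimate(calls, family_of = c(p1 = "A", p2 = "A", p3 = "B",
                                               p4 = "B", p5 = "B", p6 = "A"))
  expect_equal(est$n_selfed, 1L)
  expect_equal(est$ratio_pct, 100 / 3)
  expect_equal(est$contaminant_pct, 100 / 3)
  pf <- est$per_family
  expect_equal(pf$n_contaminant[pf$family == "B"], 2L)
  all_cont <- data.frame(progeny_id = "x", overall = "contaminant")
  expect_true(is.nan(selfing_estimate(all_cont)$ratio_pct))
  expect_error(selfing_estimate(calls[0, ]), "no progeny")
})

test_that("undetected-outcross probability is the maternal pollen mass product", {
  f2 <- allele_freqs(c(0.6, 0.4), labels = c("100", "102"))
  expect_equal(expected_undetected_outcross(list(L1 = c("100", "102")),
                                            list(L1 = f2)), 1.0)
  f <- allele_freqs(c(0.2, 0.1, 0.7), labels = c("100", "102", "104"))
  mg <- list(L1 = c("100", "102"), L2 = c("100", "102"), L3 = c("100", "102"))
  expect_equal(expected_undetected_outcross(mg, list(L1 = f, L2 = f, L3 = f)),
               0.3^3)
  expect_error(expected_undetected_outcross(mg, list(L1 = f)), "absent")
})

test_that("cumulative curve at the full panel equals the one-shot classification", {
  sim <- simulate_population(simulation_config(
    selfing_rate = 0.4, n_progeny = 50, seed = 8))
  prog <- sim$truth$progeny_id
  full <- selfing_estimate(classify_progeny(sim$panel, "F01", prog))$ratio_pct
  cv <- cumulative_selfing_curve(sim$panel, "F01", prog, k_values = 10,
                                 n_reps = 5, seed = 99)
  expect_equal(cv$mean_ratio_pct, full)
  expect_equal(cv$se_ratio_pct, 0)
  expect_error(cumulative_selfing_curve(sim$panel, "F01", prog, k_values = 11,
                                        n_reps = 2, seed = 1),
               "exceeds")
})

test_that("curve draws are reproducible under a seed and decline with k", {
  sim <- simulate_population(simulation_config(
    selfing_rate = 0, n_progeny = 60, seed = 14))
  prog <- sim$truth$progeny_id
  cv1 <- cumulative_selfing_curve(sim$panel, "F01", prog, k_values = c(1, 4, 8),
                                  n_reps = 25, seed = 7)
  cv2 <- cumulative_selfing_curve(sim$panel, "F01", prog, k_values = c(1, 4, 8),
                                  n_reps = 25, seed = 7)
  expect_identical(cv1, cv2)
  expect_true(all(diff(cv1$mean_ratio_pct) <= 0))
})
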