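---
title: "Methods: duplex SSR panels and selfed-progeny identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex SSR panels and selfed-progeny identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexSSR)
```

## The problem

Outcrossing perennial grasses such as lowland switchgrass set very little
selfed seed, yet inbred development for hybrid breeding depends on knowing
which progeny of a bagged or isolated plant are truly selfed. Codominant
microsatellite (SSR) markers resolve this directly: under disomic
inheritance every offspring carries exactly one maternal allele per locus,
so an offspring whose alleles are a *subset* of the maternal genotype at
every scored locus is consistent with selfing, while any non-maternal band
proves outcrossing. `duplexSSR` implements that classification, the marker
informativeness statistics used to choose loci, the combinatorial assembly
of loci into duplex (two-locus) PCR sets, and a simulator for validating
the whole pipeline against known truth.

## Genotype model

Genotypes are codominant, disomic allele-pair calls. A locus scored from a
single band is a homozygote recorded with multiplicity two; a blank or `0`
cell is missing. Internally allele labels are band sizes in base pairs;
the familiar gel-scoring letter codes (`ab` for the maternal
heterozygote's upper and lower bands, `c`, `d`, ... for successively
smaller non-maternal bands) are a presentation layer
(`encode_band_letters()`), because sizes are what the gel reports and
letters are only a notation over them. When two progeny show bands of
equal size, they share one letter: lettering is a function of the set of
distinct non-maternal sizes, which also makes it invariant to progeny
order.

Two table dialects are read and written (`read_genotype_table()`): two
columns per locus (`<locus>a`/`<locus>b`, the layout common parentage
programs ingest) and one slash-separated column per locus. A single
filled value at a locus means different things in the two layouts: in the
slash dialect it is a deliberate one-band homozygote, whereas an isolated
single cell in the two-column layout is more plausibly a data-entry gap
and is treated as missing with a warning. Allele sizes falling outside a
marker's declared range are reported but never fatal — published range
columns are panel-specific observations, not hard bounds.

## Informativeness statistics

For allele frequencies $p_i$ estimated by gene counting (two copies per
scored individual):

* expected heterozygosity $H_E = 1 - \sum_i p_i^2$, by default with the
  unbiased small-sample factor $n/(n-1)$ over $n$ gene copies — the form
  standard parentage software reports; the plain form is a flag away;
* polymorphic information content
  $PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$;
* the single-parent non-exclusion probability NE-1P: the chance a random
  unrelated candidate shares at least one allele with a random
  Hardy-Weinberg offspring and so cannot be excluded as its sole parent.

NE-1P is *defined* here by exhaustive enumeration over offspring and
candidate genotypes; the Jamieson-Taylor closed form
$1 - (1 - 4a_2 + 2a_2^2 + 4a_3 - 3a_4)$, $a_k = \sum_i p_i^k$, is the
default fast path and is verified against the enumeration to $10^{-9}$
in the test suite (both routes are exported). Two worked anchors:
two equifrequent alleles give $7/8 = 0.875$, and four equifrequent
alleles give $43/64 = 0.671875$. Multi-locus non-exclusion is the
per-locus product, which assumes linkage equilibrium; loci are treated as
unlinked for this purpose even when they share a linkage group, since the
panel-design rule only enforces a 10 cM minimum separation rather than
independence.

Statistics are kept at full precision internally and displayed at the
field's table conventions — three decimals for statistics, one decimal
for percentages, rounded half-up (`fmt_stat()`, `fmt_pct()`); 0.8285
displays as 0.829, not 0.828.

## Progeny classification

Per locus, a progeny is `maternal_subset`, `nonmaternal_present`, or
`no_maternal_allele` relative to its mother (`locus_status()`); missing
loci are never evidence. Overall (`classify_progeny()`):

* **contaminant** — no maternal allele at `contaminant_min_loci` or more
  loci (default 2). The source description of this rule mixes "more than
  two" prose with a "(≥2)" parenthetical; the parenthetical is the
  operational definition adopted here, and it is the one consistent with
  a contaminant example discordant at every one of six loci. The
  threshold is exposed for sensitivity analysis.
* **outcrossed** — any locus with a non-maternal allele. By default a
  single `no_maternal_allele` locus below the contaminant threshold also
  counts as outcross evidence (`strict_single_mismatch = TRUE`); turning
  the flag off treats such loci as inconclusive and leaves the progeny
  `undetermined` rather than promoting it to selfed, since a locus
  sharing *no* maternal allele is never positive evidence of selfing.
* **selfed** — maternal-subset at every scored locus, with at least
  `min_scored` loci scored (default 1; the source protocol states no
  minimum, so the floor is configurable rather than hard-coded).

The selfing ratio is $100 \times selfed/(selfed + outcrossed)$:
contaminants and undetermined progeny are excluded from the denominator,
matching how published totals in this design are computed (10/65, not
10/99). When a known pollen donor is supplied, the same maternal rules
decide selfed versus hybrid; the paternal genotype only annotates hybrid
loci (count of loci whose non-maternal alleles are all paternal).

## The cumulative curve and its closed form

With few loci, many outcrosses masquerade as selfed: an outcrossed
offspring always carries a maternal gamete, so it goes undetected exactly
when its *pollen* allele is also maternal at every scored locus. Given
the maternal genotype and pollen-pool frequencies that probability is the
product over loci of the pollen mass on maternal alleles
(`expected_undetected_outcross()`). `cumulative_selfing_curve()` traces
the empirical counterpart: for each subset size $k$ it draws `n_reps`
(default 100) random loci subsets — by default at most one locus per
linkage group, mirroring random selection of unlinked duplex sets — and
reports the mean and standard error of the selfing ratio. On a
zero-selfing synthetic population the curve's mean at each $k$ matches
$100 \times E[\prod_{l \in S} m_l]$ over random subsets $S$ within
Monte-Carlo error, and drops below 0.5 % well before eight loci with
informative markers. All subset draws are seeded and reproducible; the
seed is a required argument, not an ambient state.

## Duplex assembly

Of the six published pairing criteria, four are computable from marker
metadata and two are wet-lab observations. Computable and gating:
non-overlapping allele-size ranges separated by at least `min_gap_bp`
(default 10 bp), and map distance — different linkage groups always pass,
same-group pairs need `min_cm` (default 10 cM). Recorded but not gating:
PIC (used as the assembly weight instead) and the preference for
tri-nucleotide-or-longer repeat units (gating only when
`prefer_longer_motifs` is set). Pass-through metadata flags: duplex
amplification quality and clean two-band disomic behaviour, defaulting to
pass.

The published panel was paired empirically and no pairing algorithm is
stated, so assembly is defined here as a reproducible optimization:
exact maximum-weight matching on the compatibility graph with weight
$PIC_a + PIC_b$, via a from-scratch port of the $O(n^3)$ blossom
algorithm (`max_weight_matching()`; no installed R package offers
general-graph weighted matching). The matcher is validated against an
exhaustive matching oracle on small instances in the test suite. A
greedy descending-PIC mode is provided for contrast — on the packaged
48-marker table the exact matcher pairs all 48 markers into 24 duplexes
while greedy strands two markers. Markers are processed in lexicographic
id order so ties resolve deterministically.

Band separation (`D_min`) deliberately has two semantics: the range-based
gap computed from metadata (default, reproducible from the marker table
alone) and the observed-call separation from a genotype panel
(`observed_min_separation()`), because published separation columns mix
the two — one set in the packaged table prints 73 bp where the ranges sit
24 bp apart, reflecting sparse observed alleles. Recomputing range gaps
over the packaged 24 pairs reproduces the printed value for 23 of them
and flags exactly the three known tight sets (3, 5 and 6 bp).

Within-group adjacent-gap averaging of the packaged positions gives a
global mean neighbour distance of 25.8 cM, not the 37.7 cM quoted
alongside the source table; the computation behind that printed figure is
not stated and could not be reconstructed, so no check is pinned to it
(the per-group value for the tightest group, 8.5 cM on LG 2b, does
reproduce exactly).

## The simulator

`simulate_population()` generates what the validation populations look
like if the genetic model is taken at face value: per-locus allele
frequencies from a symmetric Dirichlet (concentration 1 by default — flat
over the simplex, giving realistically uneven microsatellite frequency
profiles), mothers as Hardy-Weinberg draws, selfed progeny as two
independent maternal gametes, outcrosses as maternal gamete plus
pollen-pool gamete, contaminants as unrelated Hardy-Weinberg draws, and
i.i.d. missing-data masking of progeny calls. Pollen pool and maternal
source share one frequency vector (panmixia) because the real
contaminants' source is unknown; loci segregate independently; there is
no mutation and no null-allele model by default (bands are scored clean
in this protocol). Defaults (10 loci, 8 alleles, one family of 46) mirror
the open-pollinated half-sib design; the power analyses in
`analysis/03_power_simulation.R` scale the family to 400 progeny so
binomial error on a recovered ratio is ~2.5 % at worst.

What passing on synthetic data does *not* show: robustness to null
alleles, allele-size binning errors, scoring mistakes, population
structure in the pollen cloud, or linkage between loci. Those failure
modes are absent from the generator by design, so the tests certify the
inference logic, not the lab protocol.

Two properties tie simulator and classifier together and are tested:
with no missing data a truly selfed progeny can never be called a
contaminant (every locus is maternal-subset), and the rate at which
outcrosses are misclassified as selfed matches
`expected_undetected_outcross()` within three binomial standard errors
across randomized configurations.

## Numerical and reproducibility choices

* All stochastic entry points (`simulate_*`, `cumulative_selfing_curve()`)
  take explicit seeds, run under a locally scoped RNG state, and restore
  the caller's stream — identical inputs give byte-identical outputs,
  including written tables.
* Problem sizes in the shipped analyses: 400 progeny per synthetic
  population, 100 subset replicates per curve point, subset expectation
  by full enumeration of $\binom{10}{k}$ loci subsets.
* Degenerate inputs have defined behaviour: a monomorphic locus has
  $PIC = 0$ and NE-1P $= 1$; an all-missing locus is an error; an empty
  denominator yields a `NaN` selfing ratio rather than a silent zero;
  letter coding fails loudly past 24 distinct non-maternal sizes.
* `assemble_duplexes()` with `objective = "max_pairs"` adds a constant
  offset (1000) to each edge weight so cardinality dominates any total-PIC
  rearrangement; with at most ~50 markers the PIC mass (< 100) cannot
  outweigh one extra pair.

## Limitations

The classifier is rule-based, not likelihood-based: it neither weighs
genotyping-error probabilities nor assigns paternity (no LOD scores, no
sibship reconstruction), and it assumes disomic inheritance throughout —
polysomic dosage scoring is out of scope. The per-marker statistics
assume Hardy-Weinberg proportions when converting frequencies into
exclusion power, which bagged or structured populations can violate.
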