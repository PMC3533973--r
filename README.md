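# duplexSSR

Microsatellite (SSR) toolkit for identifying selfed progeny in outcrossing
plants with disomic inheritance — the mating-system question behind inbred
development in switchgrass and similar wind-pollinated grasses. Bagging an
inflorescence does not guarantee selfed seed; codominant SSR genotypes do,
because every true offspring carries exactly one maternal allele per locus.

The package covers the full analysis chain:

* **Genotype model** — codominant allele-pair tables in two dialects
  (two-columns-per-locus and `161/189` slash cells), one-band homozygote
  and missing-data conventions, and the gel letter coding (`ab` maternal
  bands, `c`, `d`, ... for non-maternal bands in decreasing size).
* **Marker statistics** — allele frequencies by gene counting, observed and
  expected heterozygosity ($H_E = 1-\sum p_i^2$, optionally unbiased),
  polymorphic information content
  ($PIC = 1-\sum p_i^2-\sum_{i<j}2p_i^2p_j^2$), and the single-parent
  non-exclusion probability NE-1P, defined by exhaustive enumeration and
  served by the verified Jamieson–Taylor closed form
  $1-(1-4a_2+2a_2^2+4a_3-3a_4)$, $a_k=\sum_i p_i^k$.
* **Parentage classification** — progeny are `selfed` (maternal-subset at
  every scored locus), `outcrossed` (any non-maternal allele) or
  `contaminant` (no maternal allele at ≥ 2 loci, configurable); the
  selfing ratio is $100\times selfed/(selfed+outcrossed)$ with
  contaminants excluded, with per-family breakdowns and the cumulative
  selfing-ratio-vs-loci resampling curve plus its closed-form companion
  (the probability an outcross shows only maternal alleles).
* **Duplex design** — band-range separations, the six pairing criteria as
  computable gates/flags, and assembly of markers into duplex PCR sets by
  exact maximum-weight matching (an O(n³) blossom implementation) with
  PIC weights; linkage-map spacing reports.
* **Synthetic populations** — Hardy–Weinberg simulator with known selfing
  rate, contamination rate, pollen pool and missing-data noise, plus
  recovery experiments comparing estimates against bias-corrected truth.

## Worked example

The packaged marker table (48 loci in 24 duplex sets) and family-outcome
table are audited by the numbered scripts under `analysis/`:

```sh
Rscript analysis/01_marker_panel.R
Rscript analysis/02_selfing_analysis.R
Rscript analysis/03_power_simulation.R
```

which print, among other lines:

```
PIC mean/min/max: 0.829 / 0.622 / 0.945
NE-1P mean/min/max: 0.414 / 0.191 / 0.709
Range-based separations: 21/24 sets at/above 10 bp (87.5%); tight sets: 15, 21, 23.
Markers on 17 linkage groups; tightest group 2b with mean adjacent gap 8.5 cM; ...
  selfing ratio (contaminants excluded): 15.4% ; contaminant fraction: 34.3%.
Growth-chamber family: selfing ratio 77.3% (34 selfed / 44 progeny).
```

The marker summaries say the panel is highly informative (mean PIC 0.829;
a single locus fails to exclude a random non-parent with probability
0.414 on average, so ten loci push non-exclusion below $10^{-3}$). The
selfing analyses show the two field designs differ sharply: bagged
inflorescences yield 15.4 % selfed progeny once the 34.3 % foreign-seed
contaminants are removed, while the isolated growth-chamber plant selfed
at 77.3 %. The power simulation traces how apparent selfing in a
zero-selfing population decays from ~35 % with one random locus to below
0.5 % by eight loci, matching the closed-form undetected-outcross
probability, and recovers true selfing rates of 0/0.15/0.5/1 within
binomial error on 400 progeny:

```
  k =  1: mean  35.24% (SE 1.31), closed form  35.44%
  k =  8: mean   0.00% (SE 0.00), closed form   0.02%
true s = 0.15: estimated ratio  14.50%, bias-corrected expectation  15.00%
```

Tables land under `results/`. An interactive session boils down to:

```r
library(duplexSSR)
panel <- read_genotype_table("family.tsv", dialect = "slash")
calls <- classify_progeny(panel, mother_id = "K4",
                          progeny_ids = setdiff(panel$individuals$id, "K4"))
selfing_estimate(calls)
```

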