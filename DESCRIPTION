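Package: duplexSSR
Title: Duplex Microsatellite Panel Design and Selfed-Progeny Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for microsatellite (SSR) based mating-system analysis in
    outcrossing plants with disomic inheritance. Computes per-locus
    informativeness statistics (allele frequencies, observed and expected
    heterozygosity, polymorphic information content, single-parent
    non-exclusion probability), classifies progeny as selfed, outcrossed or
    seed contaminants from maternal allele sharing, estimates selfing ratios
    with family breakdowns, resamples loci subsets to trace the cumulative
    selfing-ratio curve, assembles markers into duplex PCR sets under
    band-separation and linkage constraints via maximum-weight matching, and
    simulates progeny populations with known selfing and contamination rates
    for power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
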