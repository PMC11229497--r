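Package: cscmsieve
Title: Variant Prioritization, Read-Depth Karyotyping and Pedigree Analysis
    for Recessive and De Novo Defects in Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementation of a whole-genome-sequencing inference
    pipeline for rare congenital defects in cattle, motivated by congenital
    syndromic Chiari-like malformation (CSCM) in Holstein calves. Provides
    inheritance-scenario variant filtering (shared recessive, per-case
    recessive, dominant de novo) with per-stage funnel counts, coding
    consequence annotation with HGVS-like labels, sequence-based case/control
    association with Bonferroni control, runs-of-homozygosity and shared
    homozygosity detection, windowed depth-of-coverage calling of segmental
    monosomy and whole-chromosome trisomy with breakpoint refinement, and
    pedigree inbreeding/carrier analysis. A synthetic cohort generator plants
    every event class with known truth so recovery can be scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
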