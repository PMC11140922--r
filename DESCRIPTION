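Package: flightsift
Title: Flight-Genetics Association, Co-Segregation and Profiling Pipeline
    for Spongy Moths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrated analysis of female flight capability genetics in
    spongy moths (Lymantria dispar ssp.). Provides a synthetic cohort
    generator emulating a two-lineage, multi-colony, family-structured
    genotyping-by-sequencing design; a six-rule variant quality-control
    cascade; KING-robust kinship with unrelated-set principal component
    analysis and PC-adjusted kinship; per-locus score-test association scans
    for binary flight class and forewing length with genomic-inflation
    diagnostics and linkage-disequilibrium based candidate-gene annotation;
    an inbred-line co-segregation filter; GO-term enrichment with
    flight-category binomial over-representation and Markov clustering of
    term networks; and a replicated DAPC flight-capability profiler.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
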