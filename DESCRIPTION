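Package: recdiv
Title: Recombination Landscape Divergence and the Genomic Architecture of
    Local Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare fine-scale recombination landscapes between two
    connected populations and to relate recombination variation and structural
    variants to genomic differentiation. Implements the Population
    Recombination Divergence Index (PRDI) and the windowed Manhattan
    dissimilarity statistic (delta-r), local-background hotspot and coldspot
    calling, per-SNP Weir-Cockerham F_ST with recombination-stratified outlier
    detection and binomial window enrichment, chromosome-preserving interval
    permutation tests, missing-data-aware windowed nucleotide diversity,
    LD-versus-pedigree recombination-map residual analyses, and
    structural-variant F_ST, density, flanking-SNP linkage-disequilibrium and
    hot/coldspot enrichment analyses. A synthetic-data module generates every
    input (recombination maps, SNP and SV genotypes, LD records) with planted
    signal so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    emmeans,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
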