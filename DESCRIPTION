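Package: crossbiome
Title: Cross-Study Consistency Analysis of Microbiome Differential Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline toolkit for standardized single-study microbiome analysis
    and multi-study biomarker validation. Implements compositional
    preprocessing (prevalence filtering, zero replacement, total-sum scaling,
    rarefaction, median-of-ratios), alpha and beta diversity with ordination
    and ANOSIM, nonparametric differential abundance with fold changes and
    LEfSe-style linear discriminant effect sizes, per-group co-abundance
    networks with topology comparison, and cross-comparison consistency
    scoring (CS and WCS) with stratified cross-phenotype and
    cross-intervention validation. Ships a seeded Dirichlet-multinomial
    multi-project simulator with planted ground truth so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
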