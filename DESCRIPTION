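Package: mitocase
Title: Case-Control Analysis of Mitochondrial Genome Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control studies of the human mitochondrial
    genome from per-sample variant calls: heteroplasmy fraction
    quantification and state classification from allele depths, functional
    effect prediction under the vertebrate mitochondrial genetic code,
    conservation-index scoring against multi-species alignments, a tRNA and
    protein variant pathogenicity cascade (MitoTip quartile classes and a
    13-predictor consensus vote), haplogroup assignment against a phylotree
    of defining variants, 2x2 association statistics with Woolf confidence
    intervals, region-wise mutational burden comparisons, and principal
    component analysis of haplogroup frequency profiles. Includes a seeded
    synthetic cohort generator so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
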