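Package: rbpdiversity
Title: Comparative Analysis of RNA-Binding Protein Family Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of RNA-binding protein (RBP)
    repertoires across species: Pfam-domain-based family classification
    against a reference RNA-binding-domain catalog, family diversity and
    clan-level counting, rank-correlation statistics with bootstrap,
    leave-one-out and Fisher-z effect-size robustness analyses,
    phylogenetic generalized least squares with Pagel's lambda, clade
    expansion ratios with pseudo-count handling, within-proteome percentile
    normalization of phase-separation propensity scores, intrinsically
    disordered region summaries, transcript-region length statistics,
    orthogroup conservation classification, and a synthetic-data generator
    that produces every input table with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
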