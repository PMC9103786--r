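Package: wregdiv
Title: Cis/Trans Regulatory Divergence of W-Linked Genes from Reciprocal-Cross RNA-Seq
Version: 0.1.0
Authors@R:
    person("wregdiv", "maintainers", email = "maintainers@wregdiv.invalid", role = c("aut", "cre"))
Description: Classifies cis- versus trans-regulatory divergence and the expression
    inheritance mode (dominant, additive, over-dominant, under-dominant, conserved) of
    W-linked genes from reciprocal-cross RNA-seq TPM tables. W-linked genes are
    maternally inherited and allele-less in birds, so classification compares each F1
    female to her maternal and paternal parent breeds instead of to allele-specific
    counts. Includes exact-test differential expression with q-value FDR control, PCA
    and PERMANOVA ordination of expression profiles, a synthetic reciprocal-cross data
    generator with known per-gene ground truth, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    rtracklayer
Config/testthat/edition: 3
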