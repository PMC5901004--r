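Package: sexbiasevol
Title: Evolutionary Analysis of Sex-Biased Genes in Dioecious Plants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies genes as male-biased, female-biased or unbiased from
    replicated two-tissue RNA-seq counts and contrasts the categories for
    rates of protein evolution (branch-specific dN/dS by codon counting),
    polymorphism (pN/pS), positive selection (McDonald-Kreitman test and the
    direction-of-selection statistic) and synonymous codon usage bias
    (effective number of codons). Category statistics are sum-aggregated
    ratios with bootstrap confidence intervals and permutation contrasts.
    Includes a codon-level sequence simulator, an expression-count simulator
    and a per-site polymorphism simulator with recorded ground truth so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    edgeR,
    ape,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'genetic-code.R'
    'alignment.R'
    'sim-config.R'
    'simulate.R'
    'masking.R'
    'expression.R'
    'divergence.R'
    'polymorphism.R'
    'category-stats.R'
    'selection-tests.R'
    'codon-usage.R'
    'regression.R'
    'pipeline.R'
    'sexbiasevol-package.R'
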