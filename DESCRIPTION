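Package: frsig
Title: Minimum-Size Gene Signature Discovery by Fisher's-Ratio Ranking and
    Leave-One-Out Nearest-Neighbor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers minimal predictive gene signatures in two-class
    expression studies. Genes are scored by Fisher's ratio (squared
    difference of class means over the sum of class variances) and log2
    fold change, filtered by ratio/fold-change bands, and a minimum-size
    signature is found by recursive elimination of low-ranked genes to
    optimize leave-one-out cross-validated nearest-neighbor accuracy.
    A random network sampler estimates posterior per-gene sampling
    frequencies over high-accuracy gene subsets. Includes a synthetic
    two-class microarray generator with planted discriminatory genes and
    batch structure, matrix-level preprocessing (log2 transform, quantile
    normalization, batch-mean centering, ANOVA differential expression
    with Benjamini-Hochberg correction), and a FACT-F based fatigue
    dichotomization rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
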