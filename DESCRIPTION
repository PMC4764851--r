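Package: transevo
Title: Comparative Evolution Analyses for De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-evolution analyses of de novo assembled
    transcriptomes lacking a reference genome: ortholog-based transcript
    integrity assessment (ortholog hit ratio over reciprocal best hits),
    TPM quantification with a beta-binomial weighted-proportions test for
    differential expression and hypergeometric annotation enrichment,
    repeat-library false-positive filtering with RepeatMasker summary
    tables and ortholog-calibrated cross-species transposable-element
    activity, Grubbs-outlier scanning for gene-family expansions, Tajima
    relative-rate tests on concatenated 1:1 ortholog alignments, and a
    counting-method Ka/Ks estimator. A synthetic-data module generates
    every input format with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
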