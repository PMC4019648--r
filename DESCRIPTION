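Package: rangefindr
Title: Range Finding for Transcriptomics Experimental Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for locating the experimental "sweet spot" in a dose by
    recovery-time transcriptomics design space from a small unreplicated
    range-finding experiment. Starting from a normalized log2 expression grid
    with one sample per design-space cell, the package corrects per-subject
    effects, removes genes that drift in untreated samples, restricts the
    design space by flagging cells with transcriptome-wide (non-specific)
    responses, screens curated gene sets over the remaining cells with a
    competitive rank-based enrichment test followed by Benjamini-Hochberg
    correction and an adaptive red-to-grey colour key, and summarizes
    per-gene Pearson dose-response correlations per time point. A synthetic
    data generator with planted pathway activations, baseline drift genes,
    subject offsets and global stress cells provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
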