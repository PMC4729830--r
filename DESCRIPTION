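Package: nucspec
Title: Specificity Profiling of Engineered Nucleases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying the activity and genome-wide
    specificity of engineered, dimeric nucleases such as zinc-finger
    nucleases. Implements dual-reporter (GFP/mCherry) quadrant gating and
    enrichment analysis, bacterial growth-curve doubling-time estimation,
    SELEX read filtering and position-frequency-matrix profiling with
    two-strand alignment to an intended target, amplicon deep-sequencing
    indel quantification with one-sided Fisher exact testing against
    controls and Bonferroni correction, and unbiased off-target discovery
    from integrase-defective lentiviral vector (IDLV) capture data via 1-kb
    single-linkage clustering of integration sites, replicate-based
    filtering, ranking, and paired half-site binding-site annotation. A
    synthetic-data module generates every input with planted ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
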