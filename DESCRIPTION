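Package: saltstress
Title: Salt-Stress Treatment Evaluation and Transcriptome Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for choosing optimal salt-treatment conditions and
    screening salt-responsive genes in plant stress experiments. Implements
    TOPSIS (Technique for Order Preference by Similarity to Ideal Solution)
    multi-criteria ranking of treatment conditions from physiological
    indicator panels with Pearson-correlation indicator screening,
    FPKM-based differential-expression calling with Benjamini-Hochberg FDR
    control and fold-change filters, hypergeometric pathway over-representation
    analysis, expression-profile clustering for heat maps, and 2^-ddCt qPCR
    relative quantification with RNA-seq concordance checks. A seeded
    synthetic-data generator with planted ground truth produces every input
    the pipeline consumes, so each stage can be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    ape,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr,
    jsonlite
Config/testthat/edition: 3
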