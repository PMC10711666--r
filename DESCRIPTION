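Package: liverbench
Title: Stratification Toolkit for Injured Human Liver Organoid Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stratifying injury models in human liver
    organoids across complementary readouts: single-cell RNA-seq quality
    control, normalization and marker-based cluster annotation by
    hypergeometric over-representation; gene-signature scoring with
    expression-matched control genes and severity ratios for fatty-liver
    disease signatures; post-processing of receptor-ligand interaction tables
    (significant-interaction fractions, treatment deltas, UpSet identifier
    sets, induced pairs); Sirius red histology quantification with isodata
    auto-thresholding; delta-delta-Ct qPCR relative quantification; and the
    nonparametric statistics (Mann-Whitney U, Kruskal-Wallis, Conover post
    hoc, Benjamini-Hochberg) tying the stages together. Ships seeded
    synthetic-data generators with ground truth for every input so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
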