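Package: crisscross
Title: Quantitative Genetic Interaction Scoring for Matrix Combinatorial
    RNAi Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of matrix (criss-cross) combinatorial RNAi screens
    of univariate cell-viability phenotypes: plate-effect adjustment via
    the midpoint of the shorth, least-squares (and robust) estimation of
    per-replicate baselines and single-gene main effects under sum-to-zero
    constraints, pairwise genetic-interaction scores on the log2 scale,
    ordinary and empirical-Bayes moderated t-tests with Benjamini-Hochberg
    adjustment, Schweder-Spjotvoll false-null estimation, pseudo-ROC
    method benchmarking, interaction and interaction-profile correlation
    networks, screen quality control (replicate correlation, spatial
    matrices, Z'-factor), and a ground-truth synthetic-screen simulator
    built on an exponential growth model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
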