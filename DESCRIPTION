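Package: pharmqsar
Title: Pharmacophore-Aligned Atom-Based 3D-QSAR Modelling and Screening
    Validation for HDAC1 Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and validating ligand-based 3D-QSAR
    models of histone deacetylase 1 (HDAC1) inhibitors. Covers molecule
    ingestion and ionization at physiological pH, pruned conformer
    ensemble generation, common-feature pharmacophore elucidation and
    scoring on active ligands, feature-based rigid alignment,
    occupancy-grid partial least squares regression with internal and
    external validation (Q2, Q2F3), and virtual-screening enrichment
    metrics (enrichment factor, Guner-Henry score, yield and ratio of
    actives, ROC/AUC). Ships a seed-controlled generator of synthetic
    benzamide-like libraries with a planted pharmacophore and
    property-matched decoys so the whole pipeline can be exercised and
    tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
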