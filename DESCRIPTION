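Package: cellcage
Title: Placement, Transcript Aggregation and Multimodal Analysis for Hydrogel CellCage Enclosures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational toolkit for flow-cell experiments in which hydrogel
    compartments ("CellCage Enclosures", CCEs) are photopolymerized on demand
    around live cells. Provides the geometric model of lanes and mRNA capture
    spots, the unconstrained and capture-spot-aware CCE placement algorithms
    with iterative overlap resolution, photomask rasterization, spot-to-CCE
    transcript aggregation with quality control, barnyard species assignment,
    signature scoring and rank-based differential expression, per-instance
    image quantification with shape-feature embeddings and an impairment
    robustness harness, longitudinal phenotype rule classification, and the
    paired imaging+transcriptomics statistics (elastic-net models with
    bootstrap stability selection, signed-rank preranked gene-set enrichment,
    and interaction-term linear models). Seeded synthetic-data generators with
    planted ground truth make every stage testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    glmnet,
    nnet,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    uwot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
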