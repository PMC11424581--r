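Package: rejunet
Title: Multiscale Regulatory Network Analysis of Rejuvenation Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A unified pipeline for multiscale analysis of single-cell
    transcriptomic rejuvenation experiments. From quality-controlled
    expression matrices and differential-expression tables it builds
    inhibition-dominant transcriptional regulatory networks by pruning a
    signed prior knowledge network, scores and classifies transcriptional
    master regulators by Boolean activation simulation, selects
    differentially active signaling intermediates, extracts crosstalk
    components between regulatory and signaling networks, and scores
    ligand-receptor cell-cell interactions. A synthetic-data module with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cellcomm.R'
    'crosstalk.R'
    'io.R'
    'pruning.R'
    'qc.R'
    'rejunet-package.R'
    'scoring.R'
    'synthetic.R'
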