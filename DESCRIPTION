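Package: somscape
Title: Self-Organizing Map Portrayal of Tumor Transcriptome Landscapes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements self-organizing map (SOM) portrayal of bulk tumor
    transcriptomes: expression matrices are reduced to a two-dimensional
    metagene grid whose per-sample images ("portraits") expose spot-like
    modules of co-expressed genes. On top of the trained map the package
    detects overexpression spot modules, scores gene-set signatures per
    sample (GSZ), orders samples along a principal-tree trajectory with
    pseudotime, builds per-metagene hazard-ratio prognostic maps with a
    derived risk score, and quantifies intra-patient heterogeneity across
    multiple lesions. A synthetic-cohort generator with planted modules,
    subtypes, liver-like contamination and survival structure provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    cluster,
    igraph,
    limma,
    EBImage,
    data.table,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
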