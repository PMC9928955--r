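Package: proteoRegion
Title: Multi-Region Quantitative Proteomics, Kinase Enrichment and
    Synaptic Puncta Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for comparing tandem-mass-tag (TMT) proteomic and
    phosphoproteomic abundance tables between two prenatal-exposure groups
    (PME vs PSE) across multiple brain regions: total-amount normalization,
    per-feature abundance ratios and t-tests, hierarchical clustering of
    differential features, kinase-substrate enrichment analysis (KSEA
    z-scores with FDR correction), hypergeometric over-representation
    analysis against GMT term databases, cross-region term-set overlap and
    cosine similarity, confidence-filtered interaction-network k-means
    subclustering on a spectral embedding, and quantification of anatomical
    synapse density from two-channel 3D image stacks (exclusion masking,
    Laplacian-of-Gaussian puncta detection, juxtaposition pairing). A
    synthetic-data generator with known ground truth emulates the 16-sample
    two-group study design so every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    tiff,
    car,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
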