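Package: spacomod
Title: Localized Gene Co-Expression Modules in Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless analysis engine for exploring localized gene
    co-expression in 2D/3D spatially resolved transcriptomics (SRT) data.
    Projects per-annotation average expression from a single-cell RNA-seq
    reference onto spatial coordinates by label correspondence, selects
    transcriptomically similar cell subsets (by annotation label, by
    breadth-first flood-fill over a transcriptomic k-nearest-neighbour
    graph, or by explicit index lists), scores genes within a selection by
    differential mean expression, Moran's I spatial autocorrelation with
    normality Z-scores, or Pearson correlation with a spatial axis, groups
    the retained genes into modules by hierarchical clustering under
    1 - Pearson distance, and annotates modules with Gene Ontology terms
    through an offline hypergeometric overrepresentation engine or the
    g:Profiler / ToppGene web APIs. Includes a synthetic-data generator
    with planted gradients, hotspots and cell-type markers, h5ad/HDF5
    readers and writers, and a batch pipeline driver with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    httr
Config/testthat/edition: 3
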