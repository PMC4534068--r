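Package: simplicialUnmix
Title: Unmixing Bulk Tumor Genomic Data with Simplicial Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers genomic profiles of unobserved pure cell populations and
    per-tumor mixture fractions from bulk genomic data (e.g. normalized
    RNA-seq expression) by fitting a structured union of low-dimensional
    simplices -- a simplicial complex -- to the point cloud of tumor
    profiles, rather than a single bounding simplex. The pipeline reduces
    dimension by PCA, partitions samples into putative subsimplices with
    geodesic-distance k-medoids clustering, fits a noise-tolerant simplex to
    each cluster under a minimum-spanning-tree-regularized objective,
    quantifies vertex uncertainty by bootstrap, merges indistinct vertices
    across subsimplices into a single complex, and extracts a tumor
    phylogeny as the minimum spanning tree over merged vertices. Includes a
    synthetic-data generator for tree-structured validation scenarios with
    known ground truth, evaluation metrics (vertex and mixture-fraction
    RMSD), and single-simplex and Gaussian-mixture baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    mclust,
    jsonlite,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bootstrap.R'
    'evaluate.R'
    'geodesic.R'
    'pipeline.R'
    'preprocess.R'
    'simplexfit.R'
    'simplicialUnmix-package.R'
    'synthetic.R'
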