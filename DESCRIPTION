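Package: clustraj
Title: Quantifying the Clusterness and Trajectoriness of Single-Cell Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores a point cloud (typically a PCA-reduced single-cell
    RNA-seq dataset) for how cluster-like or trajectory-like its geometry
    is, using five complementary metrics: the entropy of the diffusion
    pseudotime (DPT) pairwise-distance distribution, the entropy of
    zero-dimensional persistent-homology merge heights, the magnitude of a
    greedy walk over K-means centers, a geodesic adaptation of Ripley's K
    contrasted against a uniform reference, and the area under a mutual
    k-nearest-neighbor reachability curve. Includes seeded generators for
    two-dimensional cluster-like and trajectory-like benchmark datasets, a
    UMAP "geometric landscape" built from simulated scores onto which new
    datasets are projected and classified, a lightweight scRNA-seq
    preprocessing pipeline (quality control, normalization, highly
    variable genes, PCA), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    Matrix,
    RSpectra,
    igraph,
    jsonlite,
    stats,
    utils,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
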