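Package: hierseg
Title: Global-to-Local Brain Segmentation by Hierarchical Spectral
    Clustering of Jacobian Maps
Version: 0.1.0
Authors@R:
    person("GENFI", "Methods", email = "methods@example.org", role = c("aut", "cre"))
Description: Population-level, data-driven segmentation of tensor-based
    morphometry Jacobian maps by recursive binary spectral clustering
    (correlation affinity, normalized Laplacian, Nystrom eigenvector
    estimation with averaging, consensus k-means), together with the
    segmental statistical framework built on top of it: segmental size
    (mean Jacobian) tested with covariate-adjusted Student's t tests,
    segmental shape (size-normalized Jacobian patterns summarized by
    principal components retained by parallel analysis) tested with
    canonical correlation analysis, and Benjamini-Yekutieli false
    discovery rate control over the pooled family of segments, contrasts
    and features. Includes NIfTI-1 input/output, a synthetic Jacobian
    cohort generator with planted hierarchical covariance structure for
    validation, thresholded significance maps, weighted Jacobians, Dice
    overlap comparisons and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
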