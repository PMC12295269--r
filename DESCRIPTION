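Package: metabolda
Title: Concomitant-Metabolite Normalization and Exhaustive LDA Panel
    Search for Plasma Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnostic modeling of targeted plasma metabolomics
    cohorts measured as relative abundances (area-under-curve values).
    Implements preprocessing (named sample exclusion, below-LOD handling,
    per-family three-standard-deviation outlier filtering), normalization by
    a concomitant metabolite selected per biochemical family through
    iterative regression scoring, residual-based group contrasts with
    Benjamini-Hochberg correction and residual Pearson correlation matrices,
    two-class linear discriminant analysis on residuals with
    posterior-probability thresholding and leave-one-out cross-validation,
    and exhaustive enumeration of k-metabolite panels ranked by
    classification performance. Includes a synthetic cohort generator that
    reproduces the statistical structure the analysis assumes, so the whole
    pipeline is testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    MASS,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
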