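Package: pcadsc
Title: Group-Aware PCA with Centroids, Rays, Trends and the Dispersion
    Separability Criterion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Principal component analysis augmented for group comparison in
    molecular profiling matrices (genes/probes in rows, samples in columns):
    per-group centroids, sample-dispersion rays, ordinal trend trajectories,
    and dual-variable coloring, together with the Dispersion Separability
    Criterion (DSC), a trace-of-scatter-matrix statistic that quantifies
    between-group versus within-group dispersion, with a label-permutation
    test p-value. Includes delimited/MatrixMarket matrix input, sample
    annotation alignment, feature filtering, a synthetic-data generator for
    batch-shift, temporal-drift and hidden-dichotomy scenarios, and a simple
    per-batch mean-centering correction for before/after quantitation of
    batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
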