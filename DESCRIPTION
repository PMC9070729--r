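Package: fosquant
Title: Semi-Automated c-Fos Extraction and Quantitation for Brain Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies c-Fos immunoreactivity on DAB-stained brain
    sections. Detects dark nuclear blobs with a filter chain (rolling-ball
    background subtraction, mean and Gaussian smoothing, morphological
    opening) followed by area and minimum-intensity gating; maps named
    atlas region outlines onto section images via least-squares homography
    fitting; reports per-region signal densities in signals per square
    millimetre; validates automatic output against manual annotation with
    count- and area-level sensitivity and precision; and provides the
    downstream statistics (pairwise Pearson correlation matrices, Ward
    hierarchical clustering with autoscaling), social-interaction-test
    scoring rules, and a fully ground-truthed synthetic-data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
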