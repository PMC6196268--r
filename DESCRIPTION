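Package: nkmir
Title: miRNA Signature Discovery for Natural Killer Cell Subsets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Differential-expression and sparse-classification workflow for
    discriminating CD56bright from CD56dim natural killer (NK) cell subsets
    from miRNA microarray intensities. Implements the preprocessing chain
    (detection floor, log2, quantile normalization, batch adjustment, median
    centering), univariate fold-change/adjusted-p signatures with
    bi-clustering, an l1+l2 penalized sparse linear classifier with
    stability selection over nested cross-validation, Monte-Carlo
    cross-validation with Kolmogorov-Smirnov significance, delta-delta-Ct
    qPCR quantification, hypergeometric gene-set over-representation, and a
    synthetic-data generator that emulates the paired two-batch study design
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
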