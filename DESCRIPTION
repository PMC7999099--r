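Package: ospca
Title: Orthogonal Smoothed Principal Component Analysis for Ordered Metabolome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Smoothness-constrained principal component analysis for metabolome
    (and other omics) data in which samples carry a time course or rank order.
    Implements ordinary PCA, smoothed PCA with a first- or second-difference
    roughness penalty on the score sequence, orthogonal smoothed PCA (OS-PCA)
    which recasts the smoothed decomposition as a covariance-maximizing
    eigenvalue problem with an auxiliary score, and an OS-PCA variant for
    repeated-measurement designs built on a replicate-averaging operator.
    Because OS-PC loadings of autoscaled data are correlation coefficients
    between the auxiliary score and each metabolite, the package provides
    t-tests of loadings with Benjamini-Hochberg false-discovery-rate control
    for metabolite selection, a synthetic-data generator with known planted
    structure, CSV input/output helpers, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
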