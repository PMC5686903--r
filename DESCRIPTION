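Package: apisa
Title: Affinity-Propagation-Guided Iterative Signature Biclustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Biclustering of gene-expression matrices by the iterative
    signature algorithm (ISA) with seeds selected and thresholded per
    sample group found by affinity propagation clustering. Includes an
    overlap-corrected effective-number-of-biclusters statistic, subtype
    capture tables against reference labels (e.g. PAM50 calls),
    region-wise DNA-methylation beta-value profiling restricted to
    bicluster sample sets, and seeded generators of planted-bicluster
    expression and methylation data for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
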