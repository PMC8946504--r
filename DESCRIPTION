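Package: gcnrepo
Title: Co-Expression Network Drug Repositioning with Prognostic Gene Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual-cohort prognostic gene screening (univariable Cox and
    optimal-cutoff Kaplan-Meier analyses with Benjamini-Hochberg correction
    and a cross-cohort consensus of signature prognostic genes), thresholded
    Spearman gene co-expression networks with Walktrap module detection and
    transitivity filtering, hypergeometric module concordance across cohorts,
    network-topology hub and target selection with a gene essentiality
    filter, and drug repositioning by matching compound perturbation
    signatures to shRNA knockdown signatures with median-rank aggregation.
    Includes a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
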