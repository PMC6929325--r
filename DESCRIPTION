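Package: jaccardtest
Title: Statistical Significance of Jaccard/Tanimoto Similarity for
    Presence-Absence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hypothesis tests for the Jaccard/Tanimoto similarity
    coefficient between binary presence-absence vectors, as used in
    species co-occurrence analysis.  Provides the centered coefficient
    (observed similarity minus its expectation under independence), an
    exact p-value by enumeration of the underlying multinomial state
    space, a delta-method asymptotic approximation, a measure
    concentration algorithm that brackets the exact p-value within a
    user-chosen accuracy, and a bootstrap empirical null.  Includes an
    all-pairs screening pipeline with Storey-type q-value false discovery
    rate control and a simulation harness for calibration and FDR
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
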