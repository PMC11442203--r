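Package: cellfp
Title: Cellular Function Fingerprint Similarity for Multi-Component Drug
    Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the components of multi-compound (traditional
    medicine) preparations to marketed drugs by PathSim meta-path
    similarity on a compound-target-pathway heterogeneous network,
    clusters compounds on the resulting fingerprint distances, screens
    similar drugs at a median distance threshold, and quantifies
    per-indication pharmacological-effect coverage (ATC code, GO term,
    drug and cluster-group coverage with a combined ratio). Also
    transfers ATC codes and GO terms from most-similar drugs and calls
    the regulation direction of drugs on shared biological processes
    from expression z-score signatures. Includes a synthetic-data
    generator with planted mechanism groups for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
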