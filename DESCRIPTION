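Package: betadecay
Title: Partitioned Beta-Diversity Decay over Space, Season and Latitude
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partitions pairwise Jaccard dissimilarity between repeated
    community samples (trapping events) into species replacement and
    richness difference using the Podani family of presence/absence
    indices, computes the pairwise covariates that drive distance decay
    of similarity (great-circle distance, circular day-of-year distance,
    mean absolute latitude), fits site-pair-balanced weighted linear
    models of each component, and assesses the contribution of every
    model term with permutation log-likelihood-ratio tests that permute
    site attributes or sampling dates rather than individual pairs.
    A configurable metacommunity simulator with latitudinal, spatial-decay
    and seasonal structure supports calibration and power studies of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
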