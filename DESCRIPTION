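Package: ovisel
Title: Hierarchical Resource Selection from Insect Oviposition Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates insect resource selection at two spatial scales from
    per-substrate egg counts. A two-level extension of Manly's resource
    selection model describes within-patch choice between two resource types
    and between-patch choice driven by patch composition, each governed by a
    single selection coefficient on [0, 1]. The package provides the
    deterministic forward model, multinomial maximum-likelihood estimation
    with multi-start optimization and profile-likelihood confidence
    intervals, a brute-force grid oracle, a synthetic-experiment generator
    emulating two-patch choice assays with seven canonical substrate
    arrangements, and a bootstrap slope statistic that classifies
    associational susceptibility and resistance between the two resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
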