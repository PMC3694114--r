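Package: connmap
Title: Gene-Expression Connectivity Mapping with Signed-Rank Reference Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Connectivity-mapping analysis for drug repositioning. Builds
    signed-rank reference profile databases from compound-treatment
    differential-expression statistics, constructs platform-mapped gene
    signatures from ranked differential-expression tables (including a
    minimal-size selection loop targeting a false-discovery-rate budget),
    scores signatures against compound reference sets with
    randomization-based significance and Bonferroni family-wise control,
    quantifies the stability of each significant connection under
    single-gene-omission perturbation, and compares candidate-compound
    lists across platforms with exact hypergeometric overlap tests and
    sign-concordance summaries. Includes a synthetic-data generator that
    plants signature-compound connections of tunable strength so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
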