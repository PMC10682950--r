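Package: polyqsim
Title: Monte Carlo Lineage Dynamics of Expanded CAG-Repeat Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time, seeded Monte Carlo simulation of the
    intergenerational dynamics of expanded CAG-repeat (polyglutamine) alleles
    under selection, segregation distortion, meiotic repeat instability and
    genetic anticipation. Implements a simplified allele-frequency recursion
    p' = p * w * antcoeff * 2k in which an anticipation coefficient derived
    from an age-specific fertility schedule penalises carriers whose age at
    onset cuts into the reproductive window. Ships curated parameter presets
    for spinocerebellar ataxia types 2 (ATXN2) and 3 (ATXN3/MJD), ensemble
    fate statistics (elimination, fixation, persistence), a fitness-SD
    sensitivity sweep, tidy accessors, ggplot2 plots and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
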