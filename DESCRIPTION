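Package: towge
Title: Optimally Weighted Permutation Tests for Gene-Environment
    Interaction of Rare and Common Variants
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based permutation score tests for gene-environment (GE)
    interaction effects of rare and/or common genetic variants in sequencing
    association studies. Implements the test of an optimally weighted
    combination of GE interaction terms (TOW-GE), its variable-weight
    extension combining rare- and common-variant interactions over a grid of
    mixing weights with a nested min-p permutation calibration (VW-TOW-GE),
    and modified weighted-sum (WSS) and collapsing (CMC) burden comparators
    evaluated as permutation score tests on residualized data. Includes a
    synthetic genotype/trait generator and an experiment harness for type-I
    error and power studies, tidy results throughout, and a small
    command-line front end.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
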