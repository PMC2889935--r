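Package: refgenopt
Title: Optimal Reference-Gene Subset Selection for qRT-PCR Normalization
Version: 0.1.0
Authors@R:
    person("refgenopt", "developers", email = "refgenopt@example.org",
           role = c("aut", "cre"))
Description: Selects optimal subsets of candidate reference (housekeeping)
    genes for qRT-PCR normalization by estimating the unstructured covariance
    matrix of the genes' log-transformed expression levels (or threshold
    cycles) and computing the variance of the log normalizing factor -- the
    log geometric mean -- for every possible gene subset. Robust selection
    uses bootstrap 95% upper confidence limits and mean ranks of the
    normalizing-factor variance across all subsets (criteria A, B and C).
    Includes the geNorm pairwise-variation stability ranking and an
    independence-assuming (diagonal-covariance) comparator as baselines,
    plus a scenario-driven simulation engine for sensitivity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
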