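Package: kinnet
Title: Household Social Network Fusion and Dietary Influence Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fuses multi-reporter egocentric survey data into household
    social networks via kinship-term canonicalization, classifies ties
    generationally, computes tie-strength-weighted assortativity and
    relationship-category descriptives, and fits cross-classified dyadic
    mixed models of perceived health importance together with
    cluster-correlated (GEE) logistic models of dietary behaviours on
    network-average characteristics. Includes a synthetic household-survey
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
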