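Package: referralnet
Title: Referral Networks Between Health Facilities: Descriptives and
    Exponential Random Graph Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds binary directed patient-referral networks between
    health facilities from roster and referral-record tables, computes
    gatekeeping descriptives (density, tier-to-tier flows, in-degree,
    betweenness centrality), and fits directed exponential random graph
    models (ERGMs) with edges, isolates, geometrically weighted in-degree,
    dyadic distance and facility-covariate terms.  Estimation is by
    maximum pseudolikelihood and Monte-Carlo maximum likelihood with a
    tie/no-tie Metropolis sampler; simulation-based goodness-of-fit and
    inverse-logit tie-probability scenario prediction are included, along
    with a synthetic two-district data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
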