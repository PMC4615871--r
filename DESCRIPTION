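Package: hemaclone
Title: Neutral Clone-Size Dynamics of Stem-Cell-Driven Hematopoiesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the clone size distribution of lentivirus-marked hematopoietic
    stem cell (HSC) lineages tracked through viral integration site (VIS) read
    counts. Implements a neutral three-pool model (HSCs, transit-amplifying
    progenitors with a carrying-capacity-regulated Hill growth law, differentiated
    peripheral blood) as birth-death-immigration master equations; provides exact
    negative-binomial steady-state clone-size laws, Poisson read-sampling
    transforms, deterministic integration of the truncated master equations, an
    exact-event and tau-leaping stochastic simulator of clonal repopulation, and
    maximum-likelihood inference of the effective HSC differentiation rate a and
    the composite regulation-by-sampling parameter R, from which the number of
    actively contributing HSCs is estimated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
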