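Package: exclusim
Title: Cultural Repertoire Patterns from Non-Copying Social Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Individual-based simulation of behavioural repertoires in six
    ape-like populations whose agents can innovate latent behaviours and be
    socially triggered to re-innovate them, but can never copy behavioural
    forms. Implements the method-of-exclusion census used in field studies of
    ape culture (customary/habitual/present/absent/ecological-explanation
    levels and the A-D distribution patterns), together with experiment
    harnesses for parameter sweeps, census snapshots, and the population-size
    versus cultural-repertoire correlation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
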