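Package: vgpanel
Title: Ontology-Driven Virtual Gene Panel Design and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs virtual gene panels (VGPs) for rare-disease diagnosis by
    propagating curated gene-disease associations over a disease-ontology
    directed acyclic graph (such as Mondo). Implements seven panel-expansion
    strategies: the original closure (OR), fixed one- and two-level roll-ups
    taking all ancestor paths or the minimum-size ancestor (1UAP, 2UAP, 1UMP,
    2UMP), and threshold-based roll-ups that climb until a term's gene closure
    exceeds a size threshold (TH k AP, TH k MP). Evaluates panels against
    patient case sets with coverage, median intersection and expected
    number of genes to analyse, supports threshold sweeps, and ships a
    synthetic-data generator emulating whole-exome diagnostic cohorts so the
    full pipeline runs without restricted patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
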