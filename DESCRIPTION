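Package: fluxcontrast
Title: Comparative Constraint-Based Flux Sampling and Metabolomic Index Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing central-metabolic states of two cell types with
    constraint-based modeling. Builds context-specific metabolic networks from
    transcript and protein presence calls, computes flux balance and flux
    variability by linear programming, draws uniform steady-state flux samples
    by hit-and-run Markov chain Monte Carlo, and contrasts per-reaction flux
    distributions to detect shifted or reversed reactions such as succinate
    dehydrogenase (Complex II) under ischemia-like constraints. Also provides
    targeted-metabolomics index statistics: intra-sample metabolite ratios,
    adenylate energy charge, fold changes, Benjamini-Hochberg correction, and
    the pi-value gene-ranking score. A synthetic-data layer (toy electron
    transport chain network, negative-binomial expression counts, log-normal
    metabolite abundances) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
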