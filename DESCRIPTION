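Package: sigconnect
Title: Resistance Signature Discovery and Connectivity-Based Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving transcription-factor-driven drug-resistance
    signatures from drug-sensitivity-annotated expression cohorts and for
    repurposing compounds that reverse them by connectivity scoring. Implements
    AUC tertile stratification of cohorts, signal-to-noise gene ranking,
    average-rank signature combination, weighted Kolmogorov-Smirnov gene set
    enrichment with permutation significance, transcription-factor target
    screening, and the two-tailed weighted connectivity score pipeline
    (WTCS, NCS, tau, median summary scores). A synthetic-cohort generator with
    planted ground truth (a latent TF-activity program driving both target-gene
    expression and drug-response AUC, plus a planted signature reverser in a
    reference compendium) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
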