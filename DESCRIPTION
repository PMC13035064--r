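Package: startlescreen
Title: Acoustic Startle Habituation and Prepulse-Inhibition Screen Analysis
Version: 0.1.0
Authors@R:
    person("Startle Screen", "Developers", email = "startlescreen@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for larval-zebrafish acoustic-startle drug
    screens in nf1 mutants. Builds the 60-stimulus screen and 50-stimulus
    habituation stimulus schedules, simulates per-larva startle response
    datasets (Bernoulli short-latency C-bend responses with intensity-dependent
    baseline rates, short-ISI habituation decay, prepulse suppression, latency
    and kinematic draws, non-responder larvae), computes per-larva habituation,
    prepulse-inhibition, initiation and kinematic statistics with the
    non-responder exclusion rule, calls compound hits by z-scoring treated
    group means against pooled non-treated control distributions at the
    one-sided 99% level, tests target-class enrichment with Fisher's exact
    test, maps voxelwise group differences in registered brain ratio volumes
    with Mann-Whitney z-scores under Benjamini-Hochberg false-discovery-rate
    masking, and provides background-corrected fluorescence, ELISA replicate,
    Punnett-expectation and classifier PPV/NPV quantifications.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
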