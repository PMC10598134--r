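Package: ccsdelta
Title: Collision Cross Section Shifts of Post-Translationally Modified
    Peptides from Trapped Ion Mobility Data
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying how post-translational
    modifications shift peptide collision cross sections (CCS) measured by
    trapped ion mobility spectrometry. Reads MaxQuant-style evidence tables,
    aligns runs with spiked reference peptides by run-wise median deviation
    of inverse reduced mobility and retention time, converts aligned
    mobilities to CCS with the Mason-Schamp equation, filters and aggregates
    replicate features, matches modified peptides to their unmodified
    counterparts, and computes per-modification median relative CCS shifts
    with one-sample Wilcoxon tests and Benjamini-Hochberg correction,
    charge-state profiles, mass and retention-time correlations, and
    sequence-dependent CCS-shift gradients within per-charge ion clouds.
    Includes a synthetic evidence-table generator with known ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
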