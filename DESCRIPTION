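Package: flysleep
Title: Sleep, Starvation Resistance and Metabolite Phenotyping for Drosophila Activity-Monitor Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for Drosophila melanogaster
    sleep and starvation-resistance experiments. Parses TriKinetics
    Drosophila Activity Monitor (DAM) beam-break files, annotates traces
    with Zeitgeber time and feeding condition, scores sleep bouts with the
    standard five-minute immobility rule, and computes per-fly sleep
    phenotypes (total sleep, bout number and length, waking activity,
    percent change in sleep under starvation). Estimates starvation
    resistance as the interpolated LD50 (hours to 50% death) from vial
    survival censuses, normalizes whole-body glucose and triglyceride
    plate measurements with control-genotype quality control, and couples
    the phenotypes through pairwise tests, nested ANOVA/MANOVA,
    per-population regressions, and linear and Bayesian (MCMC) models of
    starvation resistance. A semi-Markov behavioral simulator generates
    complete synthetic experiments with a ground-truth ledger for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
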