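Package: tavnspipe
Title: Analysis Pipeline for Sham-Controlled taVNS Crossover Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis toolkit for transcutaneous auricular vagus
    nerve stimulation (taVNS) crossover experiments with short (3.4 s) and
    long (30 s) stimulation protocols. Implements resting-pupil preprocessing
    with full exclusion bookkeeping, pupillary-light-reflex parameterization
    (latency, constriction dynamics, redilation times), EEG band-power
    extraction via Morlet wavelets, a from-scratch spatio-temporal
    cluster-based permutation test, Go/No-Go and stop-signal scoring with
    SSRT estimation, salivary alpha-amylase secretion normalization, and the
    difference-score statistical layer (paired tests, MAD outlier removal,
    Friedman baseline checks, random-intercept mixed models). A synthetic-data
    module generates every input modality with known ground truth so the full
    pipeline runs and is testable without access to raw study recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    lme4,
    lmerTest
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
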