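Package: sonictal
Title: Seizure Indices and Acoustic Dosimetry for Focused-Ultrasound-Enhanced
    Antiepileptic Drug Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of chronic temporal-lobe-epilepsy
    EEG studies in which transcranial focused ultrasound (FUS) is used to enhance
    the local action of a protein-bound antiepileptic drug (phenytoin). Provides a
    seeded synthetic-data generator for rodent EEG cohorts with planted ictal
    events and for paired equilibrium-dialysis concentration tables; a rule-based
    ictal-event detector (repetitive 2-20 Hz sharp-wave activity, robust
    amplitude threshold, 3 s minimum duration); per-animal seizure indices
    (count, mean duration, mean amplitude) with post/pre normalization and
    Racine-scale tallies; the accompanying statistical battery (paired t,
    one-way ANOVA with Tukey-Kramer, repeated-measures ANOVA with LSD and
    Bonferroni adjustment); and acoustic dosimetry utilities (duty cycle,
    spatial-peak intensities, mechanical index, beam FWHM, and the acoustic
    radiation force on a drug-albumin complex).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite,
    withr
Config/testthat/edition: 3
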