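Package: tlfc
Title: Time-Lapse Flow Cytometry Analysis of Sperm Capacitation Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-lapse flow cytometry (TLFC): continuous per-event
    fluorescence acquisitions during sequential reagent additions. Reads and
    writes FCS 3.1 event streams, gates viable single cells (debris, doublet
    and viability gates), computes time-binned median kinetic traces, converts
    DiSC3(5) fluorescence to absolute membrane potential through a
    valinomycin/KCl Nernst calibration, converts BCECF fluorescence to absolute
    intracellular pH through a nigericin/high-potassium titration driven by
    Henderson-Hasselbalch KOH steps, quantifies progesterone-induced calcium
    responses on normalized Fluo3 traces, classifies capacitation-associated
    changes per sample, and summarizes cohorts with paired statistics. A seeded
    synthetic event-stream simulator with ground-truth labels makes every
    pipeline stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
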