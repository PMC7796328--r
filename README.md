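# tlfc — time-lapse flow cytometry for sperm capacitation physiology

Human sperm acquire fertilizing capacity through *capacitation*, which is
accompanied by three measurable physiological changes: plasma-membrane
hyperpolarization, cytosolic alkalinization, and an enhanced intracellular
Ca²⁺ response to progesterone. Time-lapse flow cytometry (TLFC) records
cellular events continuously on a peristaltic-pump cytometer while reagents
are added to the stirred sample, capturing population kinetics with
single-cell resolution. `tlfc` implements the complete analysis pipeline for
such recordings, for reproductive-biology labs and developers of sperm
functional assays.

## What it computes

For a sample measured under non-capacitating (NC) and capacitating (CAP)
conditions:

* **Membrane potential** — DiSC₃(5) fluorescence is clamped with
  valinomycin and stepped through a KCl ladder whose targets come from the
  Nernst equation

  `Em = (RT/F) · ln([K⁺]out / [K⁺]in)`

  (120 mM internal K⁺, 20 °C: −80, −63, −52, −40, −28 mV for 5–40 mM
  external K⁺). Plateau medians are fit by least squares `F = a·Em + b` and
  the resting fluorescence is inverted to absolute mV. ΔEm = Em(CAP) −
  Em(NC) is classified hyperpolarized / unchanged / depolarized at ±5 mV.
* **Intracellular pH** — BCECF fluorescence is calibrated in nigericin/
  high-K⁺ medium titrated with KOH in 0.25-unit steps (amounts from the
  Henderson–Hasselbalch base fraction, pKa 7.55 for HEPES at 20 °C); the
  fit is linear in log₁₀(F) vs pH. ΔpHi is classified alkalinized /
  unchanged / acidified at ±0.1 units, with an NH₄Cl pulse as a
  responsiveness control.
* **Ca²⁺ response** — Fluo3 traces are baseline-normalized to
  `(F − F₀)/F₀`; `F_Peak` is the maximum bin median after progesterone,
  with ionomycin/Mn²⁺ extremes as dynamic-range QC. ΔF_Peak is classified
  at ±0.25.
* **Cohorts** — paired t or Wilcoxon signed-rank comparisons (chosen by a
  Shapiro–Wilk screen on the paired differences), one-sample tests of the
  deltas against zero, and per-category count/percentage tables.

The package also contains FCS 3.1 reading/writing, debris/singlet/viability
gating, and a seeded, ground-truth-labeled simulator of BD Accuri-like
event streams (Poisson arrivals at 700 events/s, log-normal intensities,
stimulus-driven kinetics) that makes every stage testable without
instrument data.

## Worked example

Simulate an NC/CAP pair with known resting potentials (−60 and −71 mV) and
run the full membrane-potential protocol — gating, trace binning,
valinomycin/KCl calibration, interpolation, classification:

```r
library(tlfc)

cfg <- sim_config(seed = 20)                      # 700 events/s defaults
nc  <- simulate_em_run(cfg, -60, seed = 201)
cap <- simulate_em_run(cfg, -71, seed = 202)
res <- run_protocol("em", list(nc = nc$events, cap = cap$events),
                    sample_id = "donor01", donor_class = "known_paternity")
print(res)
print(res$detail$fit_nc)
```

```
<sample_result> donor01 [known_paternity] Em: NC = -59.866, CAP = -70.909, delta = -11.043 -> hyperpolarized (ok)
<em_calibration_fit> F = -10678.6 * Em + -263369.3  (R^2 = 1.000, p = 1.2e-09, 5 points)
```

The pipeline recovers the true potentials to a fraction of a millivolt: the
sample hyperpolarizes by 11 mV upon capacitation (beyond the ±5 mV band, so
it is classified "hyperpolarized"), and the calibration line fitted from
the five KCl plateau medians is reported with its R². The result carries a
QC block (gate retention fractions, fit R², control verdicts); a QC failure
marks the result `"flagged"` without suppressing the numbers.

A thin command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/tlfc.R", package="tlfc"))') \
    simulate em --seed 7 --out /tmp/sim
```

with subcommands `inspect`, `simulate`, `em`, `ph`, `ca` and `cohort`
(exit codes: 0 ok, 3 QC-flagged, 4 input error).

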