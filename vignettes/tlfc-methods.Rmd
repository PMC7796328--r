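---
title: "Time-lapse flow cytometry: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-lapse flow cytometry: models, calibrations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlfc)
```

## The measurement problem

Time-lapse flow cytometry (TLFC) acquires cellular events continuously while
reagents are pipetted into the stirred sample tube, producing a per-event
stream (time plus scatter and fluorescence intensities) that carries
population kinetics with single-cell resolution. `tlfc` turns such streams —
from FCS 3.x files or from its own simulator — into three physiological
readouts of human sperm capacitation:

* **absolute membrane potential** (Em, mV) from the voltage-sensitive
  carbocyanine dye DiSC3(5), calibrated in situ with valinomycin and a KCl
  ladder;
* **absolute intracellular pH** (pHi) from BCECF, calibrated with nigericin
  in a high-K+ medium titrated with KOH;
* **qualitative progesterone-induced Ca2+ responses** from Fluo3 on the
  baseline-normalized scale.

Each parameter is measured in a non-capacitating (NC) and a capacitating
(CAP) aliquot of the same sample; the capacitation-associated change is the
difference `CAP - NC`, classified against a fixed band (±5 mV, ±0.1 pH
units, ±0.25 normalized units; values inside the band, boundary included,
are "unchanged").

## Gating model

Events pass three filters in a fixed order:

1. **Debris**: `fsc_a >= fsc_min` and `ssc_a >= ssc_min` (defaults 5e4 and
   2e4 a.u.). Published gates of this kind are drawn by hand on density
   plots; numeric thresholds make runs reproducible.
2. **Singlets**: the pulse-geometry ratio `fsc_h / fsc_a` must fall in
   `[0.75, 1.05]`. Aggregates have roughly additive pulse area but
   sub-additive height, so doublets drop to a ratio near 0.55.
3. **Viability**: fl1 (Fluo3 or BCECF, retained only by intact cells) must
   exceed a threshold. With `viability = "auto"` the threshold is the valley
   of the smoothed 256-bin histogram of `log10(fl1 + 1)` (5-bin moving
   average) between the two dominant modes. Because stimuli move the viable
   fl1 mode during a recording, the valley is located on the pre-stimulus
   baseline window (first 120 s) and then applied to every event. A
   two-tube variant, `auto_viability_threshold()`, places the valley between
   a heat-killed control's mode and the stained sample's viable mode.

The valley detector requires the secondary mode to carry at least 5% of the
peak histogram mass and the valley to dip below 60% of the lower peak;
sparse tail bumps and wiggles on a single mode are therefore not split, and
effectively unimodal inputs fall back to an error (for gating) or to the
plain median (for subpopulation selection). None of these numbers comes
from the source protocol, which sets gates manually; they are this
package's reproducibility conventions.

## Kinetic traces and plateau statistics

The population trace of a recording is the per-bin **median** intensity in
uniform 2-s bins (about 1,000 gated events per bin at the default
700 events/s), with bins under `min_events` flagged invalid. Responses to
an addition are read as the median over a **plateau window**
`[t_add + 90 s, t_add + 120 s)` — the last quarter of the standard 120-s
inter-addition interval, by which time an exponential response with a
20-s time constant has closed 99% of its gap.

Where a recording contains a non-responding subpopulation,
`plateau_median(..., subpop = "responding")` splits the window's
log-intensity histogram at its valley (same detector as the viability gate)
and keeps the component on the expected response side — the algorithmic
replacement for manually drawn subpopulation boxes. `subpop = "all"` is
retained for comparison.

Normalization maps a trace to `(F - F0) / F0`, with `F0` the **mean** of
the valid bin medians over the first 120 s. Whether the basal "average"
should be a mean or a median of the basal segment is ambiguous in the
source protocol; the mean is used here and exposed in the code.

## Membrane-potential calibration

With valinomycin the membrane behaves as a K+ electrode and rests at the
Nernst potential `Em = (RT/F) ln([K+]out / [K+]in)`. With
`[K+]in = 120 mM` and T = 293.15 K (acquisitions run at 20 °C room
temperature) the ladder 5, 10, 15, 25, 40 mM external K+ gives −80, −63,
−52, −40, −28 mV (each within 1 mV after rounding), which is why that
temperature — not 37 °C — is the default. HTF medium already contains about
5.05 mM K+ (4.68 KCl + 0.37 KH2PO4), so the 5 mM point is the
post-valinomycin baseline requiring no KCl addition;
`kcl_schedule_volumes()` solves the cumulative mass balance for the later
steps. Plateau medians of the Disc channel are regressed on the Nernst
targets (`F = a·Em + b`, ordinary least squares) and the resting
fluorescence is inverted through the line. Calibrations with fewer than 3
distinct potentials or R² < 0.9 are refused when the functions are called
directly; inside `run_protocol()` a low R² flags the result instead of
suppressing it. All five ladder points are used in the fit.

## pH calibration

In H+Cal medium (120 mM KCl, 25 mM HEPES, 1 mM MgCl2, 10 µM nigericin,
pH 6.0) nigericin collapses the transmembrane H+ gradient so pHi tracks
pHe. KOH additions raise pHe by 0.25 units per step up to 8.0; the amount
per step follows the Henderson–Hasselbalch base fraction
`f(pH) = 1 / (1 + 10^(pKa − pH))` with pKa 7.55 (HEPES at 20 °C):
`amount = buffer × volume × (f(pH_to) − f(pH_from))`, about 0.51 µmol per
step for 25 mM HEPES in 1 mL. The amounts telescope — the ladder total
equals the single-step closed form — which is the self-consistency check of
the schedule builder. Dilution by the KOH stock is optionally reported but
not corrected by default, since no stock concentration is prescribed.

The calibration model is linear in `log10(F)` versus pHe, reconciling the
"linear" and "logarithmic" descriptions of the fit: the published fit is
drawn on a log10-fluorescence axis. Note the published example line has a
negative slope, which is opposite to BCECF photophysics (fluorescence rises
with alkalinization); the fitting and interpolation functions accept either
sign and report it, and the simulator's generating line uses a physically
oriented positive slope (0.30 per pH unit). Each condition (NC, CAP) is
calibrated against its own H+Cal aliquot. Every determination carries an
NH4Cl pulse (20 mM at 120 s) as a responsiveness control: the calibrated
rise must exceed 0.1 pH units (strict inequality) or the result is flagged.

## Calcium responses

The progesterone response is quantified on the normalized scale only:
`F_Peak` is the maximum bin median in the window between the progesterone
addition (120 s) and the ionomycin addition (300 s). No absolute Ca2+
calibration is attempted — the ionomycin maximum and Mn2+ quench minimum
serve purely as dynamic-range QC (`min < 0 < max` on the normalized scale,
and `F_Peak` must not exceed the ionomycin ceiling). Because `F_Peak` is a
maximum over ~90 noisy bin medians, it carries a positive bias of roughly
1.7× the bin-median standard error (≈0.03 normalized units at the default
noise). This is negligible for peaks near 2 but is a few percent of small
peaks; it largely cancels in the NC/CAP difference, which is the quantity
classified. The KCl-evoked Ca2+ transients seen when co-staining with Disc
are handled by the same normalization and peak extraction applied to the
Em-protocol schedule; no separate operation exists.

## Cohort statistics

Per-sample NC/CAP values are compared with a paired test chosen by a
Shapiro–Wilk screen at α = 0.05 applied to the paired differences (the
quantity the t-test assumes normal — the source protocol does not say what
the screen is applied to): normal-looking differences take a paired t-test,
otherwise a Wilcoxon signed-rank test; the branch taken is always reported.
Per-sample deltas are additionally tested against a theoretical mean of
zero with a one-sample t-test. Zero-variance inputs return p = 1 flagged as
degenerate rather than erroring. Category tables round percentages half-up
to integers (1/6 → 17%), matching the published donut-chart arithmetic; no
multiple-testing correction is applied because comparisons are reported
individually.

## The simulator: what it emulates and what it does not

`simulate_em_run()`, `simulate_ph_run()` and `simulate_ca_run()` generate
seeded, ground-truth-labeled event streams:

* **Arrivals**: a Poisson process at 700 events/s — the acquisition flow
  rate (14 µL/min) times the working concentration (3×10⁶ cells/mL).
* **Classes**: viable 75%, dead 10%, debris 10%, doublets 5%. Scatter and
  fluorescence per class are log-normal; doublets double pulse area and
  fluorescence with 1.2× sub-additive height. These fractions are
  conventions chosen to resemble a washed swim-up sperm preparation; no
  published values exist for them.
* **Dye response**: responders follow the generating model the calibration
  assumes — `F = a·Em(t) + b` for Disc (defaulting to the published
  example's coefficients) and `log10 F = m·pH + c` for BCECF — with the
  level relaxing exponentially (τ = 20 s) to each addition's target.
  Model-mismatched (saturating) dye behavior is deliberately not the
  default: the simulator isolates pipeline correctness, not dye
  photochemistry.
* **Noise**: per-event multiplicative log-normal with CV 25% and median 1.
  The CV is a convention (no noise magnitudes are published). Median-1
  noise keeps population medians exactly on the generating curve, which is
  the right null for a median-based pipeline; a mean-1 variant would shift
  medians by ~3% but the shift cancels between calibration and
  interpolation anyway. Events are independent — cells pass the laser once,
  so no autocorrelation is modeled.
* **Not modeled**: instrument electronics, drift and clogs, dye loading
  kinetics and toxicity, spectral spillover, Ca2+ channel biophysics.

Passing recovery tests therefore shows the pipeline inverts its own model
class correctly under realistic event statistics; it does not validate the
dye models against real instruments.

## Numerical choices and degenerate inputs

* Time is stored in seconds; FCS files honor the declared `$TIMESTEP` and
  fall back to 0.01 s/tick with a warning (the tick resolution is an
  instrument convention, not a published fact).
* Fits are ordinary least squares via `lm()`; interpolation outside the
  calibration span warns but returns (the resting point usually sits inside
  the span; the warning preserves auditability).
* Classification bands are boundary-inclusive toward "unchanged" in all
  three parameters, and the "hyperpolarization ΔEm < 5 mV" phrasing is read
  as ΔEm < −5 mV, consistent with the figure captions and with physiology.
* Empty gates return a warned empty table that downstream stages refuse;
  plateau windows with fewer than 200 events error with the count; ties in
  the valley search resolve to the middle of the minimal run.

## Problem sizes used by the shipped checks

Unit tests run reduced event rates (150 events/s) where full rates add
nothing; the end-to-end recovery checks in the test suite use the full
700 events/s defaults over 25 NC/CAP pairs (50 recordings) per parameter,
and `scripts/acceptance.R` recomputes the same quantities over 15 pairs per
parameter. Both sizes are comfortably beyond where the median-based
estimators stabilize (plateau windows hold >10⁴ events at full rate).

## Known limitations

* The pipeline assumes the dye response is within its linear (or
  log-linear) range; saturation near the extremes of the KCl or KOH ladder
  would bias the fit and is only detectable through the R² floor.
* The responding-subpopulation split is univariate and histogram-based; it
  will not separate overlapping modes closer than ~0.3 decades.
* `F_Peak` carries the max-statistic bias described above.
* Donor-class labels are user-supplied metadata; nothing in the data
  identifies them.
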