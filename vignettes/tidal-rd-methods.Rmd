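---
title: "Quantifying tidal recruitment from dynamic lung CT: models and methods"
author: "tidalRD authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tidal recruitment from dynamic lung CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidalRD)
```

## The problem

In injured lungs ventilated with low or no positive end-expiratory
pressure (PEEP), dependent airspaces can collapse at end-expiration and
reopen with the next inspiration.  This cyclic recruitment/derecruitment
(R/D) is a candidate mechanism of ventilator-induced lung injury, and it
is invisible to global mechanics: it must be imaged.  Dynamic CT of a
fixed transverse slice, acquired continuously at 20 Hz while the subject
breathes spontaneously with EAdi-proportional assist (NAVA), shows the
non-aerated compartment growing and shrinking within each breath.

`tidalRD` packages the complete analysis chain for such experiments:

1. **Aeration compartments** (`classify_voxels`,
   `compute_aeration_profile`): masked Hounsfield-unit slices are split
   into non-inflated (−100 to +100 HU), poorly inflated (−500 to −100),
   normally inflated (−900 to −500) and hyperinflated (−1000 to −900)
   compartments, with volumes, tissue weights and gas volumes from the
   linear mixing model (density `(HU + 1000)/1000` g/ml, gas fraction
   `−HU/1000`).
2. **Breath-by-breath mechanics** (`detect_breaths`, `integrate_volume`,
   `fit_multilinear`, `compute_ptp_max`, `extract_eadi_stats`): breath
   segmentation from flow zero crossings, per-breath multiple linear
   regression of the single-compartment equation of motion, and the
   resistive-corrected maximal transpulmonary pressure
   `P_TP,max = (Pao − Peso)_max − Rrs · F_peak`.
3. **CT-to-spirometry alignment** (`ct_gas_series`, `synchronize`,
   `select_breath_frames`): the frame clock is aligned to the waveform
   clock by maximizing the normalized cross-correlation between the CT
   gas-volume series and the spirometric volume, then each breath's
   end-inspiratory and end-expiratory frames are selected.
4. **R/D quantification** (`compute_rd`, `aggregate_by_peep`): per-breath
   R/D is the non-aerated volume (or weight) at end-expiration minus that
   at end-inspiration of the same cycle, normalized to end-expiratory
   lung volume and weight.
5. **Hypothesis battery** (`run_q_battery`): PEEP-response regressions,
   Wilcoxon comparisons of compartments between PEEP extremes,
   Kruskal–Wallis with Dunn–Šidák post hoc on R/D, one- and two-tailed
   Ansari–Bradley dispersion tests, and polynomial regressions of
   `P_TP,max` on PEEP.
6. **Synthetic study** (`simulate_breathing`, `simulate_ct_sequence`,
   `run_study`): a breathing simulator and a dynamic CT phantom generate
   a full PEEP-ramp study with ground truth for every downstream
   quantity.

## The breathing model

The simulator integrates a linear single-compartment respiratory system
driven by a raised half-sine muscle pressure over the inspiratory time
and passive expiration:

\[ R_{rs}\,\dot V = (1 + g)\,P_{mus}(t) - (E_L + E_{cw})\,V, \qquad
   g = \frac{\text{NAVA level}}{k_{EAdi}} \]

with airway pressure `Pao = PEEP + nava_level · (EAdi − tonic)`,
esophageal pressure `Peso = peso_baseline + Ecw·V − Pmus`, and
`EAdi = Pmus/k_EAdi + tonic`.  The transpulmonary channel therefore obeys
`Pao − Peso = (PEEP − peso0) + E_L·V + R_rs·V̇` *exactly*, which is what
`fit_multilinear` exploits (see below).  Integration uses the implicit
trapezoidal rule, so that trapezoidal re-integration of the emitted flow
reproduces the emitted volume bit for bit and the equation of motion
holds exactly at every sample before noise injection.

Respiratory drive follows the pattern characteristic of assisted
spontaneous breathing over a PEEP ramp in surfactant-depleted lungs:
rate falls linearly with PEEP (default `RR = 95.47 − 5.8·PEEP` /min,
floored at 1/min) and tidal volume rises linearly (default
`TV = 0.06 + 0.0206·PEEP` L).  The TV slope matches the pooled
regression such experiments report; the intercept is the package's own
choice of a realistic porcine rapid-shallow baseline, since a
regression intercept near zero liters is not a usable breath size.  The
effort amplitude is calibrated per PEEP by linearity (simulate one
rehearsal at unit amplitude, scale), then jittered breath-to-breath
(`tv_jitter_frac`, default 0.2, multiplicative Gaussian truncated at
0.2) — inter-breath variability is essential for the dispersion tests,
but its true distribution is not characterized; the parameter is
exposed rather than asserted.  Channel noise is additive Gaussian with
standard deviation `noise_sd_frac` (default 2%) of each channel's
dynamic range — simple and controllable; real transducer noise is more
structured.

Defaults: `Rrs = 16.7` cmH2O·s/L (the post-lavage respiratory-system
resistance such preparations show), lung elastance 30 cmH2O/L,
chest-wall elastance 8 cmH2O/L, NAVA level 2.0 cmH2O/µV,
neuromechanical coupling 2.0 cmH2O/µV, tonic EAdi 0.5 µV, inspiratory
fraction 0.35, 200 Hz waveforms, 100 Hz EAdi.  The esophageal offset
`peso_baseline` defaults to 0: it is an arbitrary transducer reference
that cancels from every within-breath and trend quantity.

## The CT phantom

The phantom is a 2-D slice (default 96×96 pixels of 0.5×0.5 mm, 5 mm
thick, elliptical lung mask) observed at 20 Hz for 100 s per PEEP step
(2000 frames).  The grid is far smaller than a clinical 512×512
reconstruction; it is an abstraction sized for routine re-analysis, not
a geometric lung model.  Lung pixels are partitioned into spatially
coherent regions (nearest-seed patches; default 1800 regions, i.e. a
few pixels each).  A `recruitable_fraction` (default 0.12, exact pixel
count) of the lung carries per-region **closing pressures** drawn from a
lognormal distribution (default mean 4, sd 4.5 cmH2O — strictly
positive and right-skewed, as airway closing pressures in lavaged lungs
are) and **opening pressures** offset above them (gap ~N(2, 0.5),
truncated at 0.5).

Region state follows the driving airway pressure of the clean
(noise-free) simulated breath: a region opens the moment pressure
reaches its opening pressure and closes after pressure has stayed at or
below its closing pressure for `close_dwell` seconds (default 0.1 s).
The dwell term models the finite time constant of airspace collapse.
It is not cosmetic: the assist pressure returns to PEEP at the
inspiratory-expiratory transition, and with instantaneous closure every
region would already be collapsed in the end-inspiratory frame,
abolishing measurable tidal R/D — precisely the behavior real lungs do
not show.  Opening remains instantaneous, the usual asymmetry in
recruitment dynamics.

Closed pixels take collapsed-tissue attenuation (−20 HU, inside the
non-aerated band).  Open and never-recruitable pixels track gas content
linearly: each pixel has a baseline gas fraction (uniform in
[0.35, 0.75]) plus a volume-coupled swing (`gas_frac_per_l`, default
0.5 /L), clamped to [0.12, 0.98] so aerated pixels can never enter the
non-aerated band; HU = −1000 × gas fraction, rounded to integers.
Because the R/D trend emerges from closing pressures relative
to PEEP, mean R/D decreases monotonically over the ascending ramp and
its breath-to-breath dispersion (driven by effort jitter through the
tidal pressure excursion) shrinks with PEEP — the two qualitative
signatures the statistical battery is designed to detect.  One phantom
lung is built per study and its region states are carried across PEEP
steps, so the descending limb sees the hysteresis of the ascending one.

Frames are generated on the breathing clock and stamped with a constant
lag (`ct_lag`, default 0.35 s) that the synchronization stage must
recover.  What the phantom does *not* emulate: 3-D geometry, gas
exchange, cardiogenic oscillations, slice-position drift, beam-hardening
or reconstruction artifacts.  Passing tests on the phantom therefore
validate the *pipeline arithmetic and inference logic*, not robustness
to scanner physics.

## Numerical and design choices

**Equation-of-motion channel.** During assisted spontaneous breathing
the airway pressure alone does not satisfy the equation of motion — the
muscle pressure is an unmeasured forcing term, and regressing `Pao` on
flow and volume recovers assist-gain-scaled coefficients rather than
respiratory mechanics.  The esophageal signal exists precisely to
remove the pleural component: `fit_multilinear` therefore fits the
transpulmonary difference `Pao − Peso` by default, recovering lung
elastance and resistance exactly on noiseless simulated breaths.  An
`"airway"` option covers passive recordings.

**Fit window.** The whole breath (inspiration plus expiration), volume
referenced to the breath start as the raw trapezoidal integral — the
per-breath drift correction used for tidal-volume reporting is *not*
applied inside the fit, because the correction's linear ramp would bias
the elastance estimate.

**Breath detection.** Zero crossings with a ±0.02 L/s hysteresis band;
segments gaining less than `min_tv` (default 0.01 L) are merged into
the preceding breath (noise crossings during long expirations would
otherwise truncate breath periods), and a trailing boundary with no
real inspiration after it is dropped.  Breaths with tidal volume below
`min_tv` or fit R² below 0.8 are flagged and excluded from downstream
statistics, with counts kept in the provenance block; the exclusion
thresholds are configurable because the field reports discarded
tracings without formal criteria.

**HU band boundaries.** The four printed compartment ranges share their
boundary values; `tidalRD` assigns a shared boundary to the denser band
(−100 → non-inflated, −500 → poorly, −900 → normally), a conservative
choice for atelectasis quantification.  In-mask HU outside [−1000, 100]
are clamped and counted, never dropped: masking, not thresholding, is
the exclusion mechanism.

**Frame selection.** Nearest offset-corrected frame to the spirometric
phase landmark (inspiratory end / breath end), robust when R/D makes
within-phase gas content non-monotone; an extremal-gas-content
alternative is available via `frame_method = "extremal"` for
sensitivity analysis.

**%eeLV denominator.** End-expiratory lung volume defaults to the total
masked slice volume (tissue + gas); a gas-only denominator is one flag
away (`rd_denominator = "gas"`), since the field's phrasing does not
fix the choice.

**Negative R/D** (more collapse at end-inspiration) is retained and
flagged, never clipped — truncation would bias the variance estimates
the dispersion tests rely on.

**P_TP ground truth.** The simulator's per-breath reference value is the
resistive-corrected maximum computed from the clean channels with the
true resistance; a purely elastic maximum (`peep − peso0 + E_L·V_max`)
is recorded alongside.  The two coincide only when the transpulmonary
peak co-occurs with peak flow, which the correction formula presumes.

**Ansari–Bradley.** Samples are centered at their own medians (the test
assumes equal locations), pooled, and scored symmetrically from both
ends with midranks for ties.  The null distribution is enumerated
exactly (dynamic programming over score sums) when the pooled size is
at most 20 and untied; otherwise a normal approximation from the
finite-population score moments is used, and the output records which.
The one-tailed alternative "lower PEEP more dispersed" maps to a small
score sum for the lower-PEEP sample.  `stats::ansari.test` (which does
not center) is used as an independent cross-check in the test suite on
pre-centered data.

**Dunn–Šidák post hoc.** Pairwise mean-rank z tests with the
tie-corrected pooled rank variance, Šidák-adjusted
(`p' = 1 − (1 − p)^m`); alongside the rank test, raw mean differences
are reported with Šidák-level normal confidence intervals from the
pooled within-group variance.  The significance flag follows the rank
test — the two summaries answer different questions and both are
emitted.

**Q2 pairing.** Compartment quantities at the PEEP extremes come from
different breaths; the signed-rank comparison pairs them by within-level
order, truncated to the shorter run.  With balanced designs this is a
neutral pairing; an unpaired alternative is a one-line change at the
call site.

**Settling.** Real protocols hold each PEEP for minutes before
acquiring; the simulator does not model slow derecruitment dynamics, so
`run_study` simply flags breaths starting before `settle_time`
(default 5 s) as settling and analyzes the rest, recording the window.

## Problem sizes and determinism

The defaults generate 100 s of 200 Hz waveforms and 2000 CT frames per
step and 11 steps per study — about one thousand analyzed breaths — and
a full `run_study()` completes in roughly two minutes on one core.  The
test suite exercises reduced geometries (32–48 pixel grids, 10–30 s
acquisitions) chosen so every oracle comparison still has tens of
breaths and hundreds of frames.  All randomness flows from explicit
integer seeds (per-step seeds derived from the master seed), and
identical seeds give bit-identical waveforms, frames and tables.

## Known limitations

- The mechanics model is linear and single-compartment; no flow-
  dependent resistance, no intrinsic-PEEP term beyond what incomplete
  exhalation produces dynamically.
- The phantom's recruitment responds to airway pressure; a
  transpulmonary- or regionally-referenced driving pressure would change
  which regions toggle at a given PEEP (not the monotone trend).
- EAdi is a deterministic transform of muscle pressure plus tonic
  baseline; no electrode noise, cardiac contamination or
  neuro-mechanical uncoupling.
- DICOM I/O is not provided; image exchange uses 16-bit multi-page TIFF
  with a YAML sidecar (HU offset 1024), which the reader pairs with
  per-frame timestamps.
- Statistical tables mirror the standard layouts (pairwise PEEP
  comparisons, ascending-vs-descending couples) but printed values from
  any particular animal experiment are not reproduction targets: the
  battery is validated on synthetic data with known ground truth.
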