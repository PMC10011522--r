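---
title: "Methods: synthetic mTLE EEG cohorts, ictal-event detection and FUS dosimetry"
author: "sonictal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic mTLE EEG cohorts, ictal-event detection and FUS dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonictal)
```

# What the package models

Transcranial focused ultrasound (FUS) can locally and transiently unbind a
highly plasma-protein-bound antiepileptic drug (phenytoin, PHT) from serum
albumin, increasing the free drug fraction at the sonicated epileptic focus.
The quantitative analysis behind such a study has five parts, each a module
of this package:

1. **Synthetic data** — seeded generators for chronic mesial-temporal-lobe
   epilepsy (mTLE) EEG cohorts with planted ictal events, and for paired
   equilibrium-dialysis concentration tables.
2. **Detection** — a rule-based ictal-event detector for single-channel
   rodent EEG.
3. **Indices** — per-animal seizure indices (ictal count, mean duration per
   event, mean amplitude per event), their post/pre normalization, and
   Racine-scale tallies.
4. **Group statistics** — paired *t*-tests, one-way ANOVA with Tukey–Kramer
   post-hoc contrasts, repeated-measures ANOVA with LSD and Bonferroni
   adjustment, assembled into cohort-level and dialysis-level reports.
5. **Dosimetry** — pulsing algebra (duty cycle, I~SPTA~), the plane-wave
   intensity-to-pressure chain, mechanical index and regulatory flags, beam
   FWHM extraction, and the acoustic-radiation-force estimate on the
   PHT–albumin complex.

No animal recordings are distributed: the original study's raw data are not
deposited, so everything numeric here is either computable in closed form
from printed constants or recovered from the synthetic generator.

# The synthetic cohort generator

`cohort_config()` defines the study conditions; its defaults *are* the
emulated design: three intervention arms (`PHT+FUS`, `PHT_ONLY`,
`FUS_ONLY`), ten animals per arm, one pre- and one post-intervention period,
each split into recording sessions.

## Background EEG

Inter-ictal background is pink (1/f power spectral density) Gaussian noise
with a single scale parameter (`background_rms`, default 50 µV). This is a
deliberate simplification: a 1/f spectrum is the standard first-order
approximation of mammalian EEG background, and one scale parameter is all
the detection threshold logic depends on. No circadian structure, state
transitions, or channel artifacts beyond the burst class below are
modelled.

## Ictal events

An ictal event is a train of biphasic sharp transients (difference of two
time-shifted Gaussians, lobe separation one sixth and width one eighth of
the repetition period) repeating at a per-event frequency drawn uniformly
from the 2–20 Hz ictal band, with raised-cosine onset/offset ramps of at
most 0.5 s. The kernel proportions were chosen so that the fundamental
repetition frequency dominates the spectrum (verified by an FFT-peak test)
while each transient still looks like a sharp wave. Event waveforms are
scaled so their RMS over the event equals `event_snr` × `background_rms`
(default SNR 8), with per-event lognormal jitter (`sdlog` 0.25).

Event **durations** are lognormal (`meanlog = log 5.5`, `sdlog = 0.5`,
giving a median of 5.5 s) left-truncated at the 3 s ictal minimum. The
truncation is a modelling decision with a purpose: every planted ictal
event is detectable by definition, so the number of ground-truth events
equals what a perfect detector should report, making the
count-conservation invariant exact. Sub-3 s activity is generated
separately as an explicit **artifact class** (default 2 bursts/h, durations
uniform on 0.5–2.5 s, at half the ictal amplitude scale), which the
detector must reject on duration.

The duration distribution itself is a choice, not an emulated fact — the
study reports only per-animal mean durations (5–7 s) — and the lognormal
was picked as the conventional positive, right-skewed option.

## Counts: overdispersion and the paired design

Between-animal ictal counts in chronic kainate models are enormously
variable (reported group SDs of the order of the group means, e.g.
145 ± 145 events/24 h). A Poisson count law cannot produce that; the
generator therefore draws a per-animal baseline rate from a gamma mixture
(shape `event_rate_dispersion`, default 1) — marginally a negative-binomial-
like law with SD ≈ mean — with a floor at `rate_floor` (default 10%) of the
group mean. The floor prevents near-zero-rate animals whose post/pre ratios
would be numerically undefined or wildly unstable, at a small cost in
dispersion (population CV ≈ 0.9 instead of 1.0, still far above Poisson).

The same study reports per-animal normalized count changes with a *small*
spread (±11–24%) despite the huge between-animal count spread. Independent
per-period draws cannot reproduce that combination; it implies that each
animal's post-period count is strongly coupled to its own baseline. The
generator therefore couples the two periods through a **partial-turnover
model**: a retained fraction of the baseline event process persists into
the post period (binomial thinning with survival probability
`retention` × min(*m*, 1), default retention 0.95, for rate multiplier
*m*), and the remainder of the post-period rate, (*m* − retention ×
min(*m*, 1)) times the baseline rate, arrives as fresh events. The
per-animal post/pre count ratio is then centred on *m* with Poisson-scale
noise rather than between-animal-scale noise; full retention would make the
identity effect degenerate (post ≡ pre), while low retention both inflates
the ratio spread far beyond the reported per-animal SDs and biases the mean
ratio upward for low-count animals (a fresh-Poisson-over-small-count
effect). Retention 0.95 keeps the ratio expectation within half a
percentage point of the configured multiplier at the default scale and the
per-animal spread near the reported ±11–24%. No per-animal effect
heterogeneity is modelled.

Default effect multipliers are calibrated to the reported per-animal mean
changes: count 0.43 / 0.73 / 1.13 and duration 0.85 / 1.22 / 1.20 for
PHT+FUS / PHT_ONLY / FUS_ONLY, amplitude 1.0 everywhere (no amplitude
change was observed). Duration multipliers act on the *truncated* mean: the
generator solves numerically for the post-period `meanlog` such that the
≥3 s conditional mean scales exactly by the configured multiplier, so the
multiplier means what it says despite the truncation.

## Placement, rendering and determinism

Events and artifacts are assigned to sessions uniformly and placed
uniformly within the session by rejection sampling, with no overlap and at
least 3 s separation (so detector merging, gap 1 s, can never fuse two
planted items); packing failures after bounded retries raise an error
rather than silently dropping events. Rendering adds the waveforms onto
the background. Every draw is a pure function of the configuration seed;
session rendering uses a sub-seed derived from (seed, animal, period,
session), so single sessions can be rendered on demand —
`run_cohort_pipeline()` uses this to stream a cohort through the detector
one session (about 14 MB at 1 h / 500 Hz) at a time.

The default sampling rate is 500 Hz rather than the 10 kHz of the
acquisition hardware: the ictal band ends at 20 Hz, so 500 Hz holds a
25-fold Nyquist margin while keeping a full cohort desk-sized. The
packaged analyses and tests use 1 h sessions (8 per period) for the same
reason; `session_hours = 3` reproduces the full 24 h-per-period design when
compute is no object.

## The dialysis generator

`dialysis_config()` emulates paired equilibrium-dialysis runs: eight
conditions (control cassette `Ctrl`, out-of-beam cassette `FO`, and the
focal cassette under six pulsing parameter sets `FF_set1–6`), with
condition means/SDs defaulting to the reported concentrations (Ctrl
0.55 ± 0.07, FO 0.59 ± 0.09, FF set 4 — 50 ms pulses at 10 Hz —
0.65 ± 0.10 µg/mL; the unreported focal sets are graded so the 50%
duty-cycle sets sit above the 25% ones). Each paired run adds a shared
Gaussian run effect (`run_effect_sd`, default 0.04 µg/mL), giving the
within-run correlation a repeated-measures analysis needs. The default of
8 paired runs follows the repeated-measures degrees of freedom printed with
the study's F statistics (F(5,35), F(2,14)), although its methods text
mentions ten measurements per set; the count is configuration, not a
resolution of that discrepancy.

# The detector

The study's events were screened by human reviewers using the rule
"repetitive 2–20 Hz sharp waves whose amplitude deviates from the
inter-ictal background, lasting at least 3 s". `detect_events()`
operationalizes this:

1. **Band-pass** 2–20 Hz: an order-4 Butterworth *magnitude* response
   applied in the frequency domain — exactly zero-phase, DC removed by
   construction. (The envelope of circular wrap-around at the record edges
   is negligible for minute-scale records.)
2. **Envelope**: sliding-window RMS of the band-passed trace (window 0.5 s,
   step 0.1 s).
3. **Threshold**: median + `threshold_k` × MAD of the envelope (default
   k = 5). Median/MAD statistics are used because ictal segments are
   heavy-tailed contaminants of the baseline; with ictal fractions of a few
   percent a single pass is sufficient (a two-pass re-estimate was
   considered and left out as unnecessary at these SNRs). Because the
   threshold is derived from the record itself, detections are invariant to
   any positive rescaling of the record — no calibration to absolute µV is
   needed.
4. **Events**: contiguous supra-threshold runs, boundaries at linearly
   interpolated threshold crossings, runs closer than `merge_gap` (1 s)
   merged, and — the hard rule — candidates shorter than `min_duration`
   (3 s) discarded. The 1 s merge gap keeps the 3 s minimum meaningful
   while healing envelope dropouts inside one event.

The `threshold_k = 5` default is a robustness choice, not an emulated
constant (the original screening was human); at the generator's default
SNR the detector reaches sensitivity ≥ 0.95 and FDR ≤ 0.05 with boundary
errors well under 0.5 s, which is what the property suite asserts. The
30 Hz low-pass mentioned for display in the original protocol is treated
as a display aid and plays no part in detection.

Envelope smoothing widens detected events by a fraction of the window on
each side (≈ +0.5 s on the duration). The bias is common to both periods,
so post/pre duration *ratios* are only mildly attenuated; this is visible
in the pipeline tests and accepted.

`match_events()` scores detections against ground truth by greedy
one-to-one matching on overlap fraction (intersection over the shorter
interval; minimum 0.5), ties broken by start-boundary error.

# Indices and normalization

The **ictal amplitude** of an event is the area under the rectified signal
divided by the event duration — trapezoid rule at native sampling — which
returns A for a constant |x| = A and 2A/π for a sinusoid. It is computed on
the band-passed trace by default (the detector fills it in); the original
figure does not state which trace was used, and the band-passed choice
makes the statistic independent of slow drift.

`compute_indices()` gives per animal × period: event count, mean duration
per event, mean amplitude per event. Periods without events keep count 0
and `NA` means. `normalize_indices()` divides each animal's post indices by
its *own* pre indices (never group means of raw indices — the mean of
per-animal ratios and the ratio of group means are different estimators,
and a regression test keeps them distinct). Animals with a zero or
undefined pre index are flagged `NA` and excluded per index, with a
message; the original report never describes such a case, so exclusion
with logging is our policy.

# Group statistics

All standard machinery is delegated to base R, behind typed result
surfaces: `stats::t.test` (paired *t*), `stats::oneway.test` (one-way
ANOVA, equal variances), `stats::aov` with an `Error(subject)` stratum
(repeated measures), `stats::TukeyHSD` (which implements the Tukey–Kramer
harmonic correction under unequal n), `stats::pairwise.t.test` with pooled
SD (Fisher's LSD), and `stats::p.adjust` (Bonferroni). Independent
hand-computed sums-of-squares and exact sign-flip enumerations serve as
test oracles, so implementation and verification never share a code path.

Decisions encoded in `analyze_cohort()`:

* Within-group paired *t*-tests are **one-tailed (post < pre)** for count
  and duration — the suppression hypothesis is directional — and two-tailed
  for amplitude.
* The original phrase "Tukey–Kramer post-hoc analysis with Bonferroni
  correction" is ambiguous (two corrections); we report Tukey–Kramer
  adjusted p-values as primary, and `lsd_pairwise(..., "bonferroni")` is
  available alongside, each labelled with its method.
* No sphericity correction by default in `rm_anova()` (matching
  conventionally printed unannotated df); Greenhouse–Geisser is available
  behind `gg_correction = TRUE`.
* Degenerate designs (a single group, zero-variance differences) skip the
  affected test with a warning rather than failing the whole report.
* Under a null cohort (identical effects in all arms) the between-group
  ANOVA rejects at its nominal rate (checked against binomial envelopes at
  α = 0.05 and 0.10 over 500 simulated cohorts). Its p-value distribution
  is close to, but not exactly, uniform: per-animal count ratios are
  integer-granular and heteroscedastic across animals, so a
  high-replicate KS test can detect the mild non-normality — a property of
  count data, not of the ANOVA implementation.

# Dosimetry

The chain, with printed-value anchors in parentheses:

* duty cycle DC = PD × PRF (50 ms × 10 Hz → 0.50);
* I~SPTA~ = I~SPPA~ × DC (5 W/cm² → 1.25 / 2.50 W/cm² at DC 25% / 50%);
* plane-wave pressure P = √(2ρcI) with degassed-water defaults ρ = 1000
  kg/m³, c = 1480 m/s (5 W/cm² → 0.3847 ≈ 0.38 MPa) — the constants behind
  the printed pressure are not stated in the original and are
  config-exposed in `medium_props()`;
* MI = P~r~/√f₀ (0.38/√0.6 → 0.49), FDA flag MI < 1.9;
* in situ P~r~ = P~r~ × (1 − 0.17) through rat skull/scalp (→ 0.32 MPa);
* albumin as a prolate ellipsoid, semi-axes (7, 1.5, 1.5) nm, surface area
  by Thomsen's approximation (p = 1.6075 → 105.19 × 10⁻¹⁸ m², matching the
  printed 105.11 to 0.08%; the exact prolate closed form gives 105.65 and
  is available behind `method = "prolate"`);
* radiation force F = 0.2 × P~r,insitu~ × (S/2) (→ 3.4 × 10⁻¹² N),
  i.e. 20% momentum absorption over the exposed half surface.

`dose_report()` chains these with one deliberate wrinkle: the pressure
entering the MI, in-situ and force steps is first rounded to two decimals,
because that is how the printed chain composes (0.3847 MPa would give
MI 0.497 ≈ 0.50, not the printed 0.49). Full-precision intermediates are
kept in the report's `exact` field. `beam_fwhm()` interpolates half-maximum
crossings linearly along the principal axes through the intensity maximum —
no peak fitting — and raises an error on truncated or single-pixel maps.

# Numerical choices and problem sizes

* Envelope lengths are computed in integer samples
  (`floor((n − w)/s) + 1`), avoiding float boundary surprises.
* The truncated-lognormal location shift is solved with `uniroot` at
  tolerance 1e-10; the sphere limit of the surface-area formula is exact.
* Fixed seeds: every stochastic test and example fixes its seed; the
  acceptance script takes the seed on its command line and derives
  per-session sub-seeds below 2³¹.
* Packaged problem sizes: the effect-recovery analyses run the default
  3 × 10 cohort at 8 × 1 h sessions per period and 500 Hz (≈ 480 rendered
  sessions, a few minutes of compute); statistical calibration suites use
  truth-level simulation only (no signal rendering), which is orders of
  magnitude faster. These sizes are the package's chosen desk-scale
  defaults; the full-scale design (3 h sessions, 10 kHz) is configurable.

# What passing tests do and do not show

The generator carries exactly the statistical structure the analysis
assumes: 1/f background, sharp-wave trains, NB-like overdispersed counts
coupled across periods, lognormal durations, Gaussian paired dialysis
samples. Recovering the printed group effects from it therefore validates
the *pipeline* (detection → indices → normalization → statistics), not the
biology: real rodent EEG has non-stationary background, electrode and
movement artifacts beyond the modelled burst class, seizure morphologies
that evolve within an event, and possibly rate drift between periods. A
detector that is near-perfect here will not be near-perfect on real
records; the package's claims about real data are limited to providing the
same analysis surface (`read_events_csv()`, EEG as CSV — no EDF reader is
bundled) once events are obtained.

# Known limitations

* No EDF I/O; records exchange as plain CSV.
* The synthetic per-animal normalized-change spread is tighter than the
  reported one (no effect heterogeneity across animals).
* Amplitude SNR is constant across an event (no waxing–waning envelope
  beyond the ramps).
* The dialysis emulator fills in unreported focal-set means by
  interpolation of the reported ordering; only Ctrl, FO and FF set 4 are
  anchored.
* Racine labels are generator annotations; no behavioral inference exists.
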