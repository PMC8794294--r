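---
title: "Measuring intraoperative nociception with fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intraoperative nociception with fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirspipe)
```

## The scientific problem

Patients under general anesthesia cannot report pain, yet noxious surgical
stimuli (skin incisions, cutting, drilling) still drive nociceptive
signalling into the cortex. Continuous-wave functional near-infrared
spectroscopy (fNIRS) measures cortical hemodynamics from scalp optodes and
is one of the few imaging modalities usable in an operating room.
`nirspipe` implements an analysis chain for such recordings: from raw
dual-wavelength optode intensities to per-region hemoglobin time series,
event-locked response summaries around painful procedures, and group
comparisons between patients who received a peripheral nerve block (NB)
and those who did not (non-NB).

Because intraoperative recordings of this kind are not publicly released,
the package ships a fully specified synthetic-session generator with known
ground truth. Every downstream stage is validated against it.

## Probe and montage

The probe model has nine sources, fourteen long-separation detectors
(nominal 30 mm source–detector separation, cortical sensitivity) and nine
short-separation detectors (8 mm, one per source, scalp sensitivity only).
The 24 long channels cover bilateral prefrontal cortex (PreFC, channels
1–12) and bilateral primary somatosensory cortex (S1, channels 13–24), and
are grouped into six analysis ROIs: lateral frontal, lateral prefrontal
and medial prefrontal cortex; superior, central and inferior S1.

The published probe description gives topology only, not coordinates, so
the packaged montage uses schematic 2D cap coordinates. The only quantity
that depends on absolute geometry is the nearest-short-channel assignment,
which is computed as the Euclidean distance from each long channel's
source–detector midpoint to each short channel's source position, ties
broken by the lowest short-channel id. With a different montage file the
assignment recomputes automatically.

For the data-quality gate the montage also carries a six-fold grouping of
the 24 channels into 4-channel QC regions (lateral PreFC left/right,
medial PreFC bilateral, and superior/central/inferior S1 bilateral). The
source description speaks of "two out of the four channels within a
cortical region" while naming only three regions, which cannot tile 24
channels; the packaged grouping keeps the 4-channel rule and covers every
channel, which we consider the faithful reading.

## Preprocessing model

The stage order is fixed and recorded in the output's provenance:

1. **Optical density.** `dOD = -ln(I / I0)` per channel and wavelength,
   with `I0` the mean over the first 30 s (configurable). The choice of
   baseline window only shifts `dOD` by a constant and is removed later by
   detrending.
2. **Wavelet motion correction.** A periodized orthonormal Daubechies
   (db4) discrete wavelet transform, five levels; detail coefficients
   larger than `k = 3` times a robust per-level scale (1.4826 × MAD) are
   zeroed. Transient motion spikes concentrate in few large detail
   coefficients; band-limited hemodynamics live in the approximation and
   survive (a 0.1 Hz test sinusoid passes with < 5% RMS distortion, a
   10-sigma spike loses ≥ 80% of its amplitude).
3. **Band-pass 0.01–0.3 Hz.** Butterworth, order 3 per pass, applied
   forward and backward with step-matched initial conditions and
   odd-reflection padding. Zero-phase filtering is essential here: the
   response peak latency (~20 s) is itself an analysis quantity and must
   not be shifted by filter delay.
4. **Modified Beer–Lambert law.** Per channel the 2×2 system
   `dOD(λ) = d · DPF(λ) · [ε_HbO2(λ), ε_HbR(λ)] · [ΔHbO2, ΔHbR] · 1e-6`
   is inverted, with concentrations in µM, source–detector separation `d`
   in cm, molar extinction coefficients from the standard Prahl
   compilation, and a differential pathlength factor of 6.0 at both
   wavelengths (configurable; the source study does not state its
   constants). ΔHbT is appended as the exact sum ΔHbO2 + ΔHbR.
5. **Short-separation regression.** Each long channel's ΔHbO2 and ΔHbR
   series is regressed (OLS with intercept) on the same species of its
   nearest short channel; the residual keeps cortical signal while shared
   scalp physiology is removed. ΔHbT is recomputed as the exact sum of the
   residual species: regressing HbT separately (as the source study did)
   would break the additivity invariant `HbT = HbO2 + HbR`, which we
   preserve deliberately. A zero-variance short channel degrades to
   mean-centering with a warning.
6. **Detrending.** Least-squares third-order polynomial fit subtracted,
   then a linear fit of the residual. Because the cubic basis contains the
   linear one, the second pass is an exact no-op mathematically; it is
   retained to mirror the documented procedure. Note that polynomial
   detrending absorbs a little genuine low-frequency signal: a 0.1 Hz
   sinusoid loses ≈ 6% RMS over a 4-minute record and < 5% over 5 minutes,
   which is why the generator's scaled sessions are kept ≥ 5 minutes.

Both a stage-by-stage R implementation and a single-pass compiled engine
exist; a test holds them equal to floating tolerance, and large simulation
studies use the compiled path.

### Data-quality gate

Channels are rated from the raw intensity spectrum: a Welch-averaged
periodogram (20-s segments) is computed per wavelength, and the channel's
prominence is the maximum power in the 0.7–2.5 Hz cardiac band divided by
the band median, taking the weaker wavelength. Prominence ≥ 10 rates
"good", ≥ 3 "average", else "poor". A single full-length periodogram was
tried first and rejected: the heavy tail of un-averaged periodogram noise
pushes pure white noise to a max/median ratio of ~8, which would have
rated noise-only channels "average". A QC region is good when ≥ 2 of its
4 channels are good, average when ≥ 2 are average or better; a subject
enters analysis with ≥ 2 regions average or better. Excluded subjects are
listed in the run manifest, never silently dropped.

## Epochs, curves and metrics

Channels are split by the operated knee: the hemisphere opposite the knee
is contralateral. Within each (side, ROI) cell the member channels are
averaged, excluding poor channels. Three 60-s epochs are extracted:

* **P1** starts at the first painful event, **P2** at the last (painful
  events are flagged in the event log; other procedures are ignored for
  anchoring but count for P0). With one painful event, P1 = P2 with a
  warning.
* **P0** is a procedure-free baseline: the longest gap between any two
  consecutive procedures (recording boundaries included) must reach
  120 s, and the 60-s window is centered in it (earliest gap on ties).

Each epoch segment is standardized against its own mean and SD ("z-scored";
the interpretation chosen for "standardized, normalized to the mean", which
makes curves comparable across patients and species), then averaged over a
10-s window slid in 1-s steps: 51 points for a 60-s epoch. A constant
segment maps to the zero curve by convention.

The per-cell nociception metric is the trapezoidal area under the
*absolute* standardized curve (unit spacing, 50 intervals): a constant ±1
curve integrates to 50. Because the curve is z-scored, this AUC measures
how *structured* the epoch is relative to its own variability — a clean
evoked response yields smooth large-magnitude windows (AUC → ~40), pure
noise averages toward zero under the 10-s window (AUC → ~10–15). Group
differences in AUC therefore express signal-to-noise differences, not raw
amplitude; this matters when interpreting the simulation studies below.

Dynamic coupling is summarized by Pearson correlations between the 15
unique ROI–ROI pairs over the same sliding windows, decimated to window
starts {0, 10, 20, 30, 40, 50} s, and averaged within pair sets: within
PreFC (3 pairs), within S1 (3), between PreFC and S1 (9), and all 15
("total"; the size-weighted identity 15·r̄_total = 3·r̄_PreFC + 3·r̄_S1 +
9·r̄_cross is a test invariant). Zero-variance windows are recorded
missing and excluded from the means.

## Inference

Group comparisons use a classical split-plot (mixed) ANOVA: nerve block
between subjects, epoch (or window start) within; the between effect is
tested against the subject-within-group mean square, within and
interaction against the subject-by-within residual. With one between and
one within factor, sequential sums of squares coincide with Type II, so
the unbalanced 11-vs-8 design needs no extra machinery; no sphericity
correction is applied. Per-cell group contrasts use pooled two-sample
t-tests (Welch optional). Each analysis table (all AUC effects; all
dynamic-correlation effects per side) forms one Benjamini–Hochberg FDR
family at α = 0.05.

## The synthetic-session generator

`sim_config()` defines the study conditions: 19 patients, 11 with a nerve
block; sessions of 25–65 min at 25 Hz; 2–12 painful procedures per
session plus non-painful ones, with margins guaranteeing a valid P0 gap.
Signal model per session:

* **Evoked responses** — gamma-kernel responses to each painful event in
  the long channels of the contralateral hemisphere. Non-NB S1: 0.41 µM
  ΔHbO2 peak at 20 s with an early dip and mild undershoot. NB S1: the
  block strongly attenuates the response — 0.1 µM, slower (30 s), no dip;
  no published NB amplitude exists, so this is the package's choice of an
  "attenuated, net-positive, slow" response. PreFC: 0.05 µM both groups
  (no group contrast). ΔHbR = −ΔHbO2/3. Per-channel-event amplitudes are
  jittered (15%) and recorded as ground truth.
* **Systemic physiology** — cardiac (1.1 Hz, 0.25 µM), respiratory
  (0.25 Hz, 0.12 µM) and Mayer-wave (0.1 Hz, 0.7 µM) sinusoids with
  slowly drifting phase, shared across channels with per-channel gains:
  0.4–0.9 for long channels and 5–10 (scalp-equivalent µM over the short
  0.8 cm path) for short channels. The high short-channel gains reflect
  that short channels sample the superficial layer at full strength; they
  are what makes the short channel a usable regressor at all, since the
  short optical path otherwise scales its concentration-equivalent noise
  up ~4.7-fold.
* **Artifacts and noise** — polynomial drift in OD; Poisson motion spikes
  (0.5/min, Gaussian bumps 0.2–1 s wide) shared in time across channels;
  white OD noise (SD 0.003/sample) plus a small AR(1) component
  (φ = 0.98, innovation SD 4e-5). The split of the noise budget is
  deliberate: the AR part dominates the narrow 0.05–0.15 Hz band where
  short-separation regression is evaluated (and cannot be removed by it,
  being channel-independent), while the white part provides the broadband
  in-epoch variability against which the z-scored AUC contrast between
  groups is expressed.
* **Forward optics** — concentrations map to intensities through exactly
  the Beer–Lambert forward model that preprocessing inverts, per-channel
  baselines drawn from 5e5–2e6 counts.

Everything is reproducible from a single seed. What the generator does
*not* emulate: photon transport through realistic head anatomy, pulse-rate
variability and waveform shape, task-correlated scalp blood flow (the
hardest confound for short-separation regression in real data),
vendor-specific noise spectra, and drug-level modulation of the response.
Passing tests therefore demonstrate internal consistency and statistical
calibration of the chain, not field performance on real recordings.

### Problem sizes for simulation studies

Multi-cohort studies (power of the group test; type-I calibration under a
matched null in which the NB group receives the non-NB response
parameters) use the `brief` profile: 300–340 s sessions at 10 Hz, a
procedure-free opening (clean P0 away from filter edges) followed by 2–3
painful procedures placed so every epoch ends well before the recording
edge. Epoch geometry (60 s, 10-s window, 1-s step), amplitudes, noise and
the 19-patient 11/8 split are identical to the study profile; only
duration and sampling rate are scaled so that a 19-session cohort runs in
under two seconds. The detection statistic is the AUC averaged over the
three contralateral S1 ROIs (the injected effect is region-wide), tested
with the split-plot group effect. At these sizes the packaged acceptance
checks run 50 effect cohorts (detection ≥ 80% required) and 400 null
cohorts (rejection rate within 5% ± 2.5%).

## Numerical choices and edge cases

* Window intervals are half-open `[t, t + w)`, 0-based seconds.
* Zero-variance epoch → zero curve; zero-variance correlation window →
  missing r; zero-variance short channel → mean-centering with warning;
  constant ANOVA response → missing F and p.
* The DWT pads to a multiple of 2^levels by even reflection and truncates
  after reconstruction; thresholding disabled (k = ∞) gives perfect
  reconstruction to ~1e-12.
* Session text round trips write doubles with 17 significant digits, so
  write→read is bit-exact.
* Demographic SDs are sample SDs (n − 1); a single-patient group reports a
  missing SD.

## Known limitations

* The quality thresholds (10 / 3) quantify a criterion that was visual in
  the original workflow; they are config keys, not calibrated constants.
* P0 can inherit lingering hemodynamics from earlier procedures in
  densely scheduled sessions; the generator's scaled profile avoids this
  by construction, real schedules may not.
* The split-plot ANOVA assumes compound symmetry across epochs; with
  three within levels and no sphericity correction, within-effect p-values
  are mildly liberal under violations (the between-group effect, the
  primary contrast, is unaffected).
* Correlations use ROI-pair series; hemisphere-pooled alternatives are
  not implemented.
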