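---
title: "Lateralized theta subsequent-memory analysis: models and methods"
author: "thetaSME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralized theta subsequent-memory analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

During virtual navigation to remembered object locations, the human
hippocampus shows slow "low-theta" (1–3 Hz) oscillations whose amplitude
carries two dissociable signals: a left-lateralized *subsequent-memory
effect* (more low-theta power while studying an object that will later be
recalled accurately) and a right-lateralized *navigation effect* (more
low-theta power while actively driving through the environment than while
standing still before a trial). thetaSME implements the complete analysis
chain needed to measure and test this dissociation in intracranial EEG
(iEEG) from a treasure-hunt style spatial-memory task — together with a
synthetic-cohort simulator that plants those effects with known ground
truth, so every stage of the pipeline can be validated without access to
patient data.

## The task model

The simulator reproduces the task design exactly: a 100 × 70 virtual-unit
rectangular arena; 40 trials per full session; four chests per trial, of
which two or three contain an object (100 object and 60 empty chests per
session); 1500-ms item displays; variable navigation epochs between
chests; one pre-trial baseline epoch per trial while the subject stands
still; and retrieval from an elevated viewpoint at one of the two short
ends of the arena, with a Yes/Maybe/No confidence report and a joystick
placement response per studied object.

Quantities the task fixes are defaults of `taskConfig()` and
`arenaConfig()` and are met exactly for every seed (the 100/60 split is
realized as exactly 20 three-object and 20 two-object trials, shuffled by
seed). Quantities the task leaves open were fixed once as simulator
defaults:

* navigation epoch durations: log-normal, median 6 s (sdlog 0.35,
  truncated to 2–20 s) — typical driving times to a visible chest;
* baseline durations: uniform 2–6 s;
* retrieval timing: 2 s of distractor plus 3 s per probed object,
  advancing the clock between trials (not modeled neurally).

## The behavioral model

Ground-truth memory success is drawn first (Bernoulli, p = 0.5 per
object); the placement error and confidence are then drawn conditional on
it. Remembered items get an isotropic Gaussian placement error (SD 6
virtual units); forgotten items respond uniformly at random with
probability 0.5 and with a 4-fold inflated Gaussian error otherwise.
Confidence thresholds on the realized error (12 and 28 units, with 6
units of Gaussian slack) make confidence degrade with error only in
expectation, emulating the empirical accuracy-by-confidence gradient.
Because neural gains are driven by the same ground truth, the behavioral
labels and the planted neural effects agree by construction (attenuated
only by labeling noise, as in real data).

Scoring follows the percentile-rank construction: the observed Euclidean
error is ranked against the errors of all candidate response locations on
a uniform grid covering the arena (default spacing 1 virtual unit, i.e.
101 × 71 = 7171 candidates). Ties receive half weight and a candidate
coinciding with the response is excluded, so the score is exactly 1 for a
perfect response and exactly 0 for the unique worst one. The grid spacing
and the tie-handling convention are our choices; the construction makes
the score distribution identical for all target locations, which is its
purpose. Memory labels use the median split over all of a subject's
responses combined with the confidence gate (Yes/Maybe only); the
in-task points economy (+200/−350, +100/−50, +50/0 by confidence, with
"correct" meaning the 13-unit response circle contains the true location)
is implemented separately because the two rules deliberately differ.

## The neural signal model

Each physical contact receives an independent realization of:

* power-law background noise (power ∝ 1/f², SD 10 µV), synthesized by
  spectral shaping of white noise with the DC bin zeroed;
* a *stationary* session-wide Poisson process (rate 1/s) of Hann-windowed
  oscillatory bursts at 3 Hz lasting 2–6 cycles, baseline amplitude
  12 µV with random phase. A burst's amplitude is multiplied by the
  hemisphere's memory gain when its centre falls in a
  subsequently-remembered encoding epoch, and by the hemisphere's
  navigation gain when it falls in a navigation epoch; everywhere else
  (forgotten encoding, empty-chest displays, baselines, retrieval) the
  gain is 1;
* a 60-Hz line sinusoid (2 µV, random phase per contact);
* band-limited 40–100-Hz noise during chest displays (2 µV), scaled by
  `hfaItemGain` when an object is shown — the high-frequency-activity
  analogue of item processing;
* optional transient artifacts (Poisson per minute, 400 µV exponential
  spikes) for testing the artifact-rejection stage.

Two design points deserve emphasis. First, bursts are placed over the
*whole session* rather than within epochs: low-frequency wavelets smear
over ±1–3 s, so any inhomogeneity of the burst process across epoch
boundaries (e.g. burst-free retrieval periods next to pre-trial
baselines) leaks into adjacent epochs and biases the navigation-minus-
baseline contrast even with all gains at 1. With a stationary process the
all-gains-1 model is a genuine null for every contrast. Second, bursts
are several cycles long and only moderately supra-noise; short
high-amplitude bursts make epochs leptokurtic enough to trip the
kurtosis-5 artifact screen on perfectly clean data (rejecting the very
epochs that carry the planted effect). With the default texture,
artifact-free rejection stays around 1–2% in the null model, and rises
steeply and monotonically once transient artifacts are injected.

One residual, deliberate bias remains: navigation epochs are on average
longer than baselines, and log of a time-averaged power estimate is
slightly higher for longer averages (Jensen effect). This mirrors the
analysis convention (average raw power over the epoch, then log) and
shifts both hemispheres' navigation contrasts equally, so it cancels in
the hemisphere × condition interaction that carries the lateralization
claim.

Independent noise *and* independent burst phases per contact mean the
planted oscillations survive bipolar referencing instead of cancelling in
the subtraction.

## Preprocessing

Bipolar referencing pairs immediately adjacent contacts on the same probe
(first minus second), locating the virtual channel at the pair midpoint;
common-mode components cancel exactly. Line noise is attenuated with a
4th-order Butterworth band-stop at 58–62 Hz applied with zero phase. We
apply the designed filter's squared magnitude response in the frequency
domain (with 3-s mirror padding): this is the steady-state equivalent of
a forward–backward pass, and avoids the numerically marginal start-up
transients of the nearly-unit-circle 8th-order recursion in polynomial
form. Pass-band gain is within 1% outside 50–70 Hz; a pure 60-Hz tone is
suppressed to well under 5% RMS.

Epochs are cut with a 3000-ms buffer per side (absorbing wavelet edge
effects; power at ≥2 Hz changes by <1% when the buffer is doubled) and
screened by the kurtosis rule: the plain (non-excess) fourth standardized
moment of the unbuffered voltage trace, per event × channel, with
threshold 5 — so Gaussian noise sits near 3 and single transients are
caught. Conventions the method leaves open and we fixed: non-excess
kurtosis; evaluation on the analysis window only (buffers excluded);
exclusion per event × electrode rather than whole events.

## Spectral analysis

Power is estimated with complex Morlet wavelets (wave number 5, read as
5 cycles per Gaussian SD, unit-energy normalized) on 50 logarithmically
spaced frequencies between 1 and 200 Hz. For long continuous recordings
`eventPower()` transforms each channel once and averages power per event
(the 0–1500-ms item window for chest events, the full epoch for
navigation/baseline), which is equivalent to buffered epoch-wise
decomposition away from the recording edges; `morletPower()` provides the
epoch-wise (optionally time-resolved) path.

Raw power is natural-log transformed, then z-scored per session ×
electrode × frequency (and × time bin for time-resolved tensors) using
the mean and SD over all encoding, navigation and baseline events;
empty-chest (no-item) events are transformed with those statistics but do
not contribute to them, since they are a control category plotted against
the others. Sample SD uses n − 1. Natural log (not dB) is fixed for test
determinism; only relative contrasts are used downstream, so the base is
immaterial. Band averages use closed intervals, so a grid frequency at
exactly 3 Hz belongs to both low theta (1–3 Hz) and theta (3–10 Hz), and
time–frequency binning uses fully contained overlapping windows: 69 bins
of 100 ms stepped 50 ms across −1.5 to 2 s, and 56 bins of 500 ms stepped
100 ms across −2.25 to 3.75 s. Navigation-epoch analyses re-centre z
values on the mean of the pre-trial baselines (mean subtraction only; the
z scale already carries the variance normalization).

## Statistics

Subject-level effects are built per electrode as the difference of
condition means of z band power (remembered − forgotten, navigation −
baseline, item − no-item), averaged over the subject's electrodes within
hemisphere. Group inference is a one-sample t-test against zero (paired
and pooled two-sample variants for the condition and hemisphere
comparisons), Bonferroni-corrected across the bands × hemispheres family
within each contrast.

Cluster-based permutation testing controls the family-wise error across
time–frequency bins: bins whose group t exceeds the two-sided parametric
p < 0.05 critical value form same-sign clusters under 4-connectivity
(1-D adjacency for time-only traces); cluster mass is the sum of member
t values; the null flips each subject's whole map sign at random (1000
permutations, seedable) and records the maximum absolute cluster mass;
p-values use the (k+1)/(n+1) convention. The cluster-forming threshold
and adjacency are our choices where the method family leaves them open.
The connected-components labeling is implemented in C++ since the
calibration suites label millions of small maps.

Spatial maps aggregate electrode effects onto target points within
12.5 mm (cortical) or 3 mm (hippocampal) with optional 4-mm-FWHM
Gaussian smoothing, excluding points with fewer than five subjects.
Their significance thresholds come from a sign-flip null: per permutation
and point, a uniformly random half (⌊n/2⌋) of subjects is flipped and the
group t recomputed; the 2.5th/97.5th percentiles of the pooled null form
the thresholds. The wording "flipping half of the values at each vertex
for each subject" is ambiguous between flipping half the subjects per
vertex and half of each subject's vertices; we implement the former.

Lateralization is tested with a two-way fixed-effects ANOVA (hemisphere ×
condition) on the subject-level 1–3-Hz effects, using type-II sums of
squares because the hemisphere groups are unbalanced in realistic
cohorts; the interaction is the quantity of interest, followed by
per-cell one-sample and across-hemisphere pooled two-sample t-tests.

Narrowband oscillations are distinguished from the aperiodic background
by robust regression (IRLS, bisquare weights, tuning constant 4.685, ≤50
iterations, tolerance 1e-8) of mean log power on log frequency over
1–50 Hz; frequencies whose residual exceeds one residual SD above the
fit are flagged, and the negated slope estimates the background
exponent.

Within-subject SEMs for condition time-courses remove each subject's mean
(restoring the grand mean) before computing per-condition SEMs.

## Decoding

Subsequent-memory success is decoded per subject with L2-regularized
(ridge) logistic regression on z power averaged over the item window, at
10 log-spaced frequencies in 1–10 Hz and 10 in 40–100 Hz (a matched
number of features per range), electrodes × frequencies as columns.
Cross-validation leaves one session out, or one trial out for
single-session subjects; held-out probabilities are pooled across folds
before computing the AUC. The penalty is fixed (glmnet lambda 1, no
internal tuning) since a single fixed model is reported; features are
already z-scaled, so no further standardization is applied (avoiding
double scaling). Significance uses 100 within-subject label
permutations (identity permutations excluded by redrawing); the
electrode sweep ranks electrodes by the maximum absolute two-sample t
across frequencies on a random half of the events and evaluates top-N
models on the held-out half, averaged over repetitions.

A caveat established during validation: with very few events per fold
(single short sessions under leave-one-trial-out), pooled-prediction AUC
is biased below chance under the null, because training-set class
composition anti-correlates with the held-out label. At the paper-like
regime the pipeline emulates — two sessions per subject, leave-one-
session-out — the null AUC is close to 0.5; calibration checks therefore
use two-session subjects.

## Problem sizes used in the validation suites

All suites run on synthetic cohorts chosen to keep a laptop-class
validation honest: shortened sessions (6–8 trials, ≈250–350 s at 500 Hz —
the full 40-trial design is the generator default and is itself verified
exactly), 3–5 contacts per probe (6–8 bipolar channels per subject),
reduced wavelet grids (e.g. 8 log-spaced frequencies over 1–8 Hz when
only the 1–3-Hz band is analysed — the grid construction is identical to
the 50-point default), 12–20 subjects per cohort, 500–1000 permutations,
and 2000-dataset calibration suites for the per-bin false-positive rate
and the cluster-level family-wise error. The planted-effect recovery
check uses 20 subjects with left memory gain 2 and right navigation gain
2 over 10 seeds and requires the full qualitative pattern (significant
left memory and right navigation contrasts, non-significant right memory
contrast, significant hemisphere × condition interaction) in at least 9.

## What the synthetic data do and do not show

The generator emulates the *statistical structure* the analysis relies
on: event timing and counts, percentile-rank behavioral scoring with
confidence-linked errors, 1/f background spectra, narrowband bursts with
condition- and hemisphere-specific amplitude, line noise, HFA item
responses, and transient artifacts. It does not emulate hippocampal
biophysics, phase–amplitude coupling, spatially structured noise
correlations between probes, non-stationary drift, or electrode
localization error. Passing the recovery suites therefore demonstrates
that the pipeline measures what it claims to measure when the planted
model holds — not that the planted model is a complete account of real
iEEG.

## Known limitations

* Ragged (variable-length) epochs are analysed time-averaged only.
* The navigation-minus-baseline contrast inherits the small positive
  Jensen bias discussed above; interaction tests are unaffected.
* The notch stage implements the band-stop's zero-phase magnitude
  response; extreme in-band transients are handled by the kurtosis
  screen, not by adaptive line-noise removal.
* Recording persistence is TSV/JSON only; recordings live in memory.
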