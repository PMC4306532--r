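---
title: "Linking pre-stimulus oscillatory amplitude and phase to saccadic reaction time: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking pre-stimulus oscillatory amplitude and phase to saccadic reaction time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Even for highly salient visual targets, saccadic reaction times (RTs) vary
four- to five-fold across trials. Part of that variability is deterministic
— driven by the experimental design (inter-trial interval, trial type and
history, fatigue and practice across blocks) — and part is spontaneous.
`prestim` implements an analysis chain that asks how much of the spontaneous
part is predicted by the amplitude and phase of pre-stimulus MEG
oscillations, and where in the visuo-oculomotor network (V1, IPS, FEF, SEF)
those predictors live.

Because no public MEG data accompany this analysis style, the package is
built around a synthetic-data generator with injected ground truth. Every
stage — saccade detection, RT correction, beamforming, time–frequency
analysis, phase statistics, group inference — is validated by parameter
recovery and null calibration on that generator.

# The generator

`sim_config()` defines a synthetic experiment; the defaults are the study
conditions the package emulates:

* **Trial schedule.** 800 trials in 4 contiguous equal blocks; trial types
  left / right single target / two-target choice, i.i.d. with probability
  1/3 each. The foreperiod (fixation-to-target interval, the ITI used as an
  RT regressor) is *non-aging*: constant hazard, implemented as an
  exponential distribution (default rate 1/0.35 s⁻¹) truncated to
  [3, 4] s, because constant hazard is the defining property invoked for
  this design. The previous-trial condition of the first trial of each
  block is a dedicated `"start"` level, excluded from the 3×3
  renormalization cells, since nothing defines it.
* **Reaction times.** `rt = 262 ms + ITI effect + condition offsets +
  block trend + amplitude coupling + residual`, with a total SD of 48 ms.
  Effect sizes default to the variance shares of the emulated behavior:
  ITI 1.2%, current×previous condition 7.9% (holding the choice-trial
  penalty at exactly `choice_penalty`, default 14 ms, and carrying the rest
  on a previous-condition repeat/alternate pattern), and blockwise linear
  trends 8.6%, with alternating-sign slopes across blocks. The
  single-vs-choice RT difference is reported inconsistently in the source
  literature (14 vs 18 ms); it is therefore an explicit free parameter
  rather than a hard-coded constant. Choice outcomes are Bernoulli
  (`choice_bias`, default 0.5), deliberately independent of everything
  else: the generator's null is that nothing before the stimulus predicts
  choice.
* **MEG epochs.** Each `ground_truth_source()` is a current dipole inside a
  single homogeneous conducting sphere (analytic field solution; radial
  dipoles are silent, so source orientations are tangential). The sphere
  replaces a multi-sphere or realistic head model on purpose: it is
  analytic and self-contained, and the lead-field interface accepts
  externally supplied forward models for real data. Sensors are radially
  oriented gradiometer-like channels on a Fibonacci-spiral spherical cap
  (default 30 channels, radius 110 mm, 75° cap). Each source emits
  band-limited Gaussian noise (center ± bandwidth/2), RMS-normalized per
  trial over the coupling window and multiplied by a smooth per-trial
  envelope factor `max(1 + d·z, 0.05)` with `z ~ N(0,1)` and depth
  `d = 0.4`. RT is coupled to the *standardized realized envelope*, so a
  source's `rt_coupling_r` is, by construction, the population correlation
  between the measurable baseline amplitude and RT.
* **Scales and SNR.** Lead fields are normalized to unit L2 norm and the
  field constant is dropped: fields are in arbitrary units, which leaves
  every correlation, contrast and localization unchanged. With
  `base_amplitude = 2` and `sensor_noise_sd = 2`, the per-channel in-band
  SNR of a default source is ≈ 1. This matters for two reasons. First,
  real MEG baselines are dominated by ongoing background activity, so an
  in-band background comparable to the signal is the realistic regime.
  Second, an adaptive beamformer facing a very strong source that sits
  slightly off the voxel grid partially cancels it (the classic
  high-SNR/mismatch signal-cancellation effect), which would make the
  generator *harder* to localize than real data; a realistic noise floor
  keeps the beamformer in its intended operating regime. The envelope
  depth 0.4 keeps across-trial envelope variation well above the intrinsic
  narrowband amplitude-estimation noise (CV ≈ 0.1 for a 10 Hz band over
  1 s), so the injected correlation is the measured correlation up to a few
  percent.
* **EOG.** The horizontal channel is a smooth sigmoid step (τ = 5 ms) of
  configurable amplitude at `target onset + rt`, signed by saccade
  direction; blinks are Gaussian bumps on the vertical channel. Violations
  (small saccades, blinks) can be injected per trial to test the exclusion
  rules against known labels.

What the generator does *not* emulate: realistic anatomy or volume
conduction, correlated background sources, microsaccades, ocular-artifact
physics beyond step-plus-blink, or head movement. Passing tests therefore
demonstrate the correctness and calibration of the analysis machinery under
a controlled model, not performance on any particular real dataset.

# Saccade detection and exclusions

EOG traces are smoothed with a Savitzky–Golay filter (order 3, window 31
samples; mirror-padded by half a window so the output keeps the input length
with no phase shift). The saccade onset is the maximum of the absolute first
difference of the smoothed horizontal trace within a [75, 700] ms search
window (the validity window [75, 500] ms is enforced separately; earliest
sample wins ties). Trials are excluded for baseline blinks (vertical
excursion beyond a threshold during the 1 s baseline), first-saccade
amplitude below half the stimulus eccentricity, directional errors on
single-target trials, latency outside [75, 500] ms, or an undetermined
onset. Exclusion is idempotent.

# The RT correction cascade and its ledger

Three regressor variants are built sequentially, mirroring the order of the
behavioral analysis: `rt_corrected` removes the linear ITI effect and
renormalizes the nine current×previous condition cells to a common mean;
`rt_detrended` additionally removes each block's linear trend and offset.
Every step preserves the grand mean (renormalization, not residualization),
which changes nothing downstream since Pearson correlations are
location-invariant. Cells with fewer than 5 trials fall back to
current-condition marginal means — the 12-cell scheme that also splits by
the previous choice outcome is deliberately not implemented, for the same
small-cell reason. A fourth variant, `rt_v1corrected`, removes the linear
association of RT with the mean V1 band amplitude, to isolate parietal and
frontal contributions beyond V1.

The `variance_ledger` reports each step's share of the raw RT variance in
two forms. The raw sequential fractions are the realized variance
reductions; they telescope exactly (`iti + condition + block + residual =
1`). They are also upward-biased for the *generating* shares, by the usual
least-squares overfit of roughly `df/n` (about one percentage point for the
9-cell step at n = 800). The `_adj` entries subtract the expected overfit
(`df` model terms × the residual mean square) from each removed sum of
squares, giving an approximately unbiased estimate of the injected share —
these are the entries to compare against generating values or across
studies.

# Source reconstruction

For each frequency band (5–15, 15–25, 25–35, 35–70, 70–100 Hz) and baseline
window ([−1, 0] or [−0.2, 0] s), a *global* (all-trials pooled) sensor
covariance is computed from zero-phase band-passed epochs. Filtering uses
the squared-magnitude response of an order-4 Butterworth applied in the
frequency domain to mirror-padded data — numerically the forward–backward
("filtfilt") filter, but one FFT per column, with the padded length rounded
up to a 2-3-5-smooth number for speed.

Beamformer weights per voxel follow the scalar (SAM-style) construction:
the source orientation is restricted to the tangential plane and chosen to
maximize unit-gain output power (the minimum eigenvector of the 2×2
`LᵀC⁻¹L`), and `w = C⁻¹l / (lᵀC⁻¹l)`, which satisfies `wᵀl = 1` exactly.
The covariance is diagonally loaded by 5% of its mean eigenvalue by default
(configurable); no loading value is canonical, and 5% is a common
middle-of-the-road choice. Per-trial source amplitude is the RMS of the
projected band-limited signal over the window — for narrowband signals this
equals the mean Hilbert envelope up to a constant, which correlations
ignore. The *correlational* image is the per-voxel Pearson r between that
amplitude and the behavioral regressor across trials; the choice contrast
is the per-voxel two-sample t between left- and right-choice trials.

ROI summaries are reported two ways: the peak of the group-average map
within an ROI (a lower bound, sensitive to voxel-level spatial reliability
across subjects) and the group average of per-subject peaks (an upper
bound).

# Virtual electrodes and time–frequency analysis

Virtual electrodes (20 V1 sites plus SEF, left/right FEF, left/right IPS)
are defined by literature MNI coordinates, mapped onto the synthetic sphere
by a single affine scale (0.75) since no individual anatomy is in scope;
the 20 V1 sites in the bundled fixture are synthetic constructions along a
calcarine-like axis. Electrode weights use a broadband 0–100 Hz global
covariance ("optimal filter" weights are not specified more precisely in
this analysis tradition; the broadband-covariance reading is documented
here), and the full-bandwidth signal is projected through them.

The Hilbert filter bank covers 5–100 Hz in 1 Hz steps with ±4 Hz zero-phase
Butterworth bands; amplitude and phase are modulus and argument of the
analytic signal, then time is decimated by 2 (plain subsampling — the
narrow bands guarantee anti-aliasing). TF correlation maps average the
amplitude in 50 ms bins per trial and correlate across trials per
(frequency, bin); maps from several electrodes are averaged on the
r-values. Correlations computed per 50 ms bin are attenuated by the
within-bin envelope-estimation noise of narrowband signals (a single
independent envelope sample per bin); when a single per-trial amplitude is
wanted — the V1 regressor, or any comparison against the windowed
beamformer amplitude — the amplitude is averaged over the band and window
first and then correlated (`tf_band_amplitude()`), which is the only
reduction commensurable with the windowed RMS statistic.

The fast/slow view median-splits trials on RT (an odd middle trial joins
the fast half, a documented convention); spectra are normalized by
subtracting the all-trial 5–70 Hz mean, band time courses by their
all-trial mean over [−2, −1] s. The r-timecourse analysis fits a
least-squares slope of r over time per subject and tests the slopes against
zero at the group level.

# Phase: quintile ITC bootstrap

Trials are stably sorted by RT and split into contiguous quintiles (the
first `n mod 5` quintiles take the extra trials). The statistic is the mean
over quintiles of the within-quintile inter-trial coherence (modulus of the
mean unit phasor) per (frequency, time) cell — if phase influences RT,
same-quintile trials are more phase-aligned than chance. The null shuffles
trials into quintiles at random (100 shuffles by default, matching the
analysis design this emulates); `t = (observed − null mean)/null SD`, with
one-sided p-values from the Gaussian tail of the shuffle null. Averaging
ITC across quintiles and then standardizing (rather than standardizing per
quintile) is the documented choice; an exact-permutation p-value option
exists for small designs. The statistic is amplitude-blind by construction.
Clusters are reported as 4-connected components spanning at least 2
adjacent frequencies and 2 adjacent time bins, and the default phase range
is 5–35 Hz (configurable).

Because the generator injects coupling through the envelope only, its phase
is null by design — which is exactly what lets the ITC machinery be
calibrated (t-values mean ≈ 0, SD ≈ 1; ~5% of cells below p = 0.05).

# Group inference

Per-subject r-values (amplitude) or t-values (phase) are tested against
zero with one-sample t-tests, per cell; r-values enter untransformed (a
Fisher-z option exists but is off by default, matching the analysis
tradition emulated). Volumetric maps additionally get sign-flip permutation
inference with max-statistic ("omnibus") correction across voxels: all
2¹² = 4096 flips are enumerated for ≤ 12 subjects (seed-free and exactly
reproducible), Monte-Carlo flips otherwise; the base statistic is the
one-sample t (the mean difference would also be valid; t is the common
choice and is documented). Families of p-values across frequencies, time
bins, ROIs and regressor types are controlled with Benjamini–Hochberg FDR.

# Numerical choices and degenerate inputs

* Zero-phase filtering: order-4 Butterworth magnitude-squared response,
  1 s mirror padding; padded FFT lengths rounded to 2-3-5-smooth numbers.
* Diagonal loading: 5% of the mean covariance eigenvalue; a singular
  covariance without loading is an error, rank-deficient pooled windows
  trigger a warning.
* Constant covariates (ITI, V1 amplitude) return the input unchanged with
  a warning; constant voxel amplitudes yield NaN correlations; constant
  regressors are errors.
* Ties: saccade-differential ties resolve to the earliest sample; RT ties
  in the quintile split resolve by trial order (stable sort).
* Zero-variance subject cells in group tests are flagged, with t = ±Inf
  and p = NA rather than a silent 0/1.
* Determinism: all generator draws derive from `sim_config$seed` (schedule,
  RT, epochs, EOG use seed, seed+1, seed+2, seed+3); per-subject seeds in
  `run_study()` are `(master %% 2e6)·1000 + subject` — valid 32-bit
  integers, independently reproducible and parallelizable.

# Problem sizes used in the tests

The test-suite and acceptance runs use desk-scale versions of the study
conditions, chosen as the smallest sizes at which the quantities of
interest are statistically meaningful: 500-trial, 30-channel subjects with
a shortened epoch for beamformer parameter recovery (20 replicates) on a
25 mm grid restricted to the sensor-covered volume; 800-trial behavioral
replicates (50) for the ledger; 12-subject null studies (100 replicates)
for familywise-error calibration; 100-shuffle ITC nulls. The full
275-channel, [−2.7, 0.7] s epoch configuration is expressible through the
same `sim_config()` but is not exercised routinely.

# Known limitations

* The spherical forward model cannot represent realistic conductor
  geometry; users with real forward solutions should supply their own lead
  fields.
* The generator's background is white sensor noise, not spatially
  correlated brain noise; beamformer output SNR on real data will be less
  favorable than in these simulations.
* Correlational images inherit the usual beamformer depth/orientation
  biases; only peak-location claims within about one grid spacing are
  supported by the recovery tests.
* The Gaussian tail of the 100-shuffle ITC null is an approximation; use
  the empirical-p option when exactness matters more than resolution.
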