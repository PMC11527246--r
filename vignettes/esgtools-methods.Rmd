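---
title: "Extracting spinal evoked potentials from multichannel surface recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting spinal evoked potentials from multichannel surface recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Somatosensory evoked potentials (SEPs) of the human spinal cord can be
recorded noninvasively with surface electrodes over the vertebral column
(electrospinography, ESG), but the signals are small — of the order of one
microvolt at the skin — and sit beneath cardiac artifacts that are an order
of magnitude larger, stimulation transients that are two orders larger, and
broadband physiological noise. `esgtools` implements an analysis chain that
makes single-trial spinal responses accessible from a dense 17-electrode
grid centred on an anatomical target (the spinous process of C6 for the
cervical cord, L1 for the lumbar cord): artifact repair, cardiac denoising,
multivariate spatial filtering, response metrics, and the statistics used to
establish such responses at the participant and group level. A synthetic
data generator with complete ground truth makes every stage testable without
access to recorded data.

## The processing chain

### Stimulation artifacts

Electrical nerve stimulation leaves a brief transient in every channel.
`detect_stim_artifact_window()` finds its extent on the grand mean over all
events and all grid channels of one patch: samples exceeding `k = 8`
baseline standard deviations form the artifact core, expanded outwards to
where the mean re-enters one baseline SD. The real criterion in practice is
visual inspection per participant; the automatic rule is an approximation,
so the result carries a `fallback` flag and can be overridden per patch from
the pipeline config (`stim$window_override`). Typical windows are a few
milliseconds around stimulus onset (about -2 to +4 ms at the cervical
level). `interpolate_artifact()` then replaces the windowed samples with a
shape-preserving piecewise cubic Hermite interpolant (PCHIP) anchored on
five context samples per side — five is enough for robust slope estimation
while keeping the anchors clear of the artifact's skirts. PCHIP neither
overshoots nor rings, which matters because any repair artifact at stimulus
time is stimulus-locked and would survive averaging.

Interpolation must precede cardiac cleanup: a 500 µV residual transient
inside an R-peak window would otherwise contaminate the least-squares fit of
the cardiac basis far beyond its own duration.

### Filtering and resampling

All filters are fourth-order Butterworth designs run forward and backward
(`filter_zero_phase()`), giving zero phase and the squared one-pass
magnitude — at a band edge the gain is exactly 0.5. Edge transients are
controlled by odd-reflection padding. The standard spinal band is
30–400 Hz with a 48–53 Hz notch; for line harmonics introduced by
stimulation hardware a comb of second-order notch sections at 50 Hz and its
harmonics is available, parameterized by a -3 dB width as a fraction of
Nyquist (default 0.003). Recordings acquired at 10 kHz are reduced to the
1 kHz analysis rate by `resample_recording()` (anti-alias corner at 0.9 of
the target Nyquist, then decimation; events are remapped by index scaling).

### Cardiac artifacts

Cardiac cleanup follows the optimal-basis-set (OBS) approach: R-peaks are
detected on the ECG channel (`detect_r_peaks()`, an envelope detector with a
300 ms refractory period; externally curated annotations are accepted
verbatim), and for each channel separately the signal in windows of
±0.5 median RR around each peak is collected into an artifact × time
matrix. The basis is the mean artifact plus the first four principal
components of that matrix; PCA is computed after removing the mean artifact,
so the basis is non-redundant (the convention is not fixed in the source
literature; uncentred PCA would make the mean and the first component nearly
collinear). Each beat's window is then fitted by ordinary least squares and
the fit subtracted. Windows of adjacent beats are clipped at the midpoint
between the peaks, edge beats are fitted on truncated windows, and samples
outside all windows are untouched.

Two properties of this operator are worth knowing. First, it is linear in
the signal once the basis is fixed, which is how the tests isolate its
action on artifact and response separately. Second, because the principal
components are estimated from the very windows they are applied to, a small
number of beats lets the basis absorb noise (in-sample overfitting shrinks
as roughly $\sqrt{5/n_\mathrm{beats}}$); with the several hundred beats of a
real session this is below 2% of the signal RMS.

### Rejection and epoching

`reject_timepoints()` applies per-role threshold rules (100 µV absolute for
spinal channels; for EEG, five standard deviations on a 1–15 Hz filtered
copy and 60 µV on a 15–45 Hz copy), with any channel exceeding the
threshold in more than half of its samples dropped as a whole instead of
masked. Epochs run from -200 to 700 ms around each stimulus with endpoints
inclusive — 901 samples at 1 kHz — and are baseline-corrected over
-110 to -10 ms; trials overlapping masked samples are excluded.

### CCAR spatial filtering

The core of the package is canonical correlation average regression (CCAR).
Let $X$ hold all single-trial segments within a short window around the
expected peak (±5 ms, i.e. 11 samples per trial at 1 kHz), concatenated in
time, and let $Y$ hold the trial average tiled once per trial. CCA finds
$w_x, w_y$ maximizing $\mathrm{corr}(w_x^\top X,\; w_y^\top Y)$ — template
matching between each trial and the average, with the template's spatial
weighting learned per participant. `train_ccar()` solves this by whitening
both covariance matrices and taking the SVD of the whitened
cross-covariance; a ridge term `regularization * trace/dim` (default
$10^{-6}$) keeps the whitening stable, and with zero regularization
rank-deficient input is a refused rather than silently truncated. Activation
patterns — the interpretable sensor-space topography of each component —
are the filter weights multiplied by the covariance of $X$. Training warns
when fewer than 50 samples per feature are available, the ratio below which
canonical correlations become unreliable.

Component selection (`select_component()`) considers the first two
components, mirroring the empirical observation that the response component
always ranks that high: a component qualifies when its filtered trial
average peaks within a tolerance (default ±5 ms) of the expected latency
(13 ms cervical, 24 ms lumbar for upper/lower-limb mixed-nerve stimulation)
and its pattern is focal over the grid target (the target electrode carries
at least half of the largest absolute pattern weight). The pattern criterion
is deliberately polarity-free: CCA is blind to sign, absolute pattern
polarity flips with the reference convention, and the selection must be
invariant under a global sign flip of the data. Polarity is instead imposed
on the component trace — the filter is multiplied by -1 if needed so the
peak has the expected direction. The filter is then applied to the entire
epoch (`apply_filter()`), yielding single-trial component traces in
arbitrary units; for lower-SNR conditions (e.g., sensory-nerve stimulation)
the filter trained on the high-SNR mixed-nerve data is applied unchanged,
which keeps selection and testing independent.

As an overfitting control, `stability_control()` retrains CCA on random
halves of the trials and computes all pairwise absolute correlations between
the resulting first-component time courses, on task epochs and on
resting-state surrogate epochs cut with identical trial timings. Repeated
genuine responses give near-perfect stability; on rest data the filters
chase noise and the correlations collapse. On the default synthetic fixture
this separation is large (about 0.99 vs 0.33); the per-participant means are
compared across participants with a one-tailed paired t test.

### Metrics

`peak_measure()` reads latency and amplitude at the extremum of stated
polarity in a search window; a peak below two baseline standard deviations
is flagged invisible and its amplitude is read at a group-level fallback
latency instead. `snr()` implements the ratio of RMS in a ±1 ms window
around the peak to the RMS of a same-length pre-stimulus window; the noise
window sits mirrored at minus the peak latency by default (the pre-stimulus
placement is ambiguous; a variant ending at -10 ms is available).
`time_frequency()` is a continuous short-time FFT (21 ms Hann window, hop of
one sample, zero-padded to 1024 points) with each frequency row divided by
its mean over a -200 to -10 ms baseline. Note the TF baseline deliberately
differs from the epoch baseline (-110 to -10 ms); both are separate config
values.

### Statistics

`one_sample_t()` / `paired_t()` report t, p, a two-sided 95% CI and
Cohen's d; an exactly-zero-variance paired contrast is reported as p = 1
with a flag rather than an error. The interaction ratio
$$\mathrm{IR} = 100\cdot\frac{(D_1 + D_2) - D_{12}}{D_1 + D_2}$$
quantifies attenuation under simultaneous two-digit stimulation relative to
the sum of single-digit responses: 0% is additivity, positive values are
integration, negative values amplification; it is scale invariant and
therefore applies to arbitrary-unit component amplitudes.

`cluster_permutation()` compares two paired condition arrays over a
channel × time grid with family-wise error control: paired t per sample, a
two-sided cluster-forming threshold at `cluster_alpha = 0.05` (positive and
negative clusters formed separately), cluster mass as the sum of t values,
and a max-|mass| null distribution over per-participant sign flips of the
differences. With twelve or fewer participants the $2^n \le 4096$ flips are
enumerated exhaustively; otherwise 1000 random flips (seeded, observed
labelling included) are used. Channel adjacency for the grid links
electrodes within 2.5 cm — the 1 cm and 2 cm neighbours but not the 5 cm
outer columns, which is why the adjacency is checked for islands and
reported. The connected-component search is implemented in C++ since the
null distribution requires clustering thousands of permutation fields.
Null simulations put the empirical family-wise error rate at about 5%
(see `scripts/acceptance.R`).

`sample_size_power()` inverts the noncentral-t power function of a
one-sample test: the smallest n whose power at noncentrality
$|d|\sqrt{n}$ reaches the target. At 90% power and one-tailed α = 0.05 it
returns n = 36 for d = 0.5 and n = 24 for d = 0.62 — the two
preregistration calculations this style of study runs.

### Robustness curves

`participant_trial_curve()` resamples single-trial amplitudes with
replacement at a grid of trial counts (default 5 to 1000 in steps of 10),
tests each resample against zero, and reports the proportion of significant
repetitions per participant and count. `group_experiment_sim()` simulates
whole experiments: participants resampled with replacement, then trials
within each occurrence (drawn independently per occurrence), trial means
per participant, and a one-sample t test across participants. Spatial
filters are trained once on all trials and reused across resamples;
retraining per repetition is out of scope for cost, and this matches how
such resampling analyses are actually run. The default test is two-sided
with a one-sided option: the underlying effects are signed, but the
published grids do not state a tail, so the conservative default is
two-sided. Under a null pool the curves sit at α; under an exact d = 1
pool they track the closed-form noncentral-t power to within Monte-Carlo
error.

## The synthetic generator

`generate_recording()` emulates a desk-scale mixed-nerve session at the
1 kHz analysis rate: a stimulus train with 763 ms inter-stimulus interval
and ±50 ms uniform jitter in 1 ms steps; a triphasic evoked template (small
initial positive lobe, main negative lobe at 13 ms, slow late positive
lobe — built as a difference of Gaussians with a 3 ms main-lobe scale,
the lobe ratios being free parameters) on a unit-norm radial-dipole
topography centred on the grid target; cardiac artifacts locked to R-peaks
drawn from a truncated-normal RR distribution (1000 ± 50 ms, minimum
300 ms) with rank-one beat-to-beat shape variability (so the 4-PC basis
provably spans it; a second variation axis is available as a stress mode)
and a large clean ECG complex on the ECG channel; 500 µV stimulation
transients over -2 to +4 ms; and white (3 µV), $1/f$ (2 µV), and 50 Hz
line noise (1 µV, harmonics at -20 dB). Each stochastic ingredient draws
from its own seeded substream, so configurations differing in one
ingredient — task vs rest, cardiac on vs off — share bit-identical
realizations of the rest. That is what lets the tests isolate the cardiac
operator's action on artifact and response exactly, and makes
`generate_resting_state()` a true surrogate run: same noise and cardiac
structure, no evoked sources, events carried along for identical trial
timings.

Planted single-trial SNR is parameterized as the signal-to-noise *power*
ratio in the source projection within the training window
(`amplitude_for_snr()`), the convention of the spatial-filter simulation
literature. It maps onto the attainable single-trial/average canonical
correlation as roughly $\sqrt{\mathrm{SNR}/(1+\mathrm{SNR})}$ — at
SNR 0.1 the training correlations come out near 0.22, the range reported
for real spinal grids, which is the consistency check behind this choice.

What the generator does not emulate: volume-conduction forward physics
(the dipole is a Gaussian falloff, not a lead field), realistic ECG
morphology beyond the parameterized template, myogenic or movement
artifacts, and spatially correlated background noise. Passing tests
therefore demonstrate correctness of the algorithms under controlled
conditions, not performance on any particular real recording.

## Numerical choices and degenerate inputs

* Sample indexing is 0-based; epochs use millisecond bounds inclusively
  (-200..700 ms at 1 kHz = 901 samples).
* Ridge regularization for CCA defaults to $10^{-6}$ of the mean diagonal;
  whitening drops directions below $10^{-12}$ of the leading eigenvalue,
  so the retained component count equals the numerical rank.
* Selection ties break to the lower component index; only the first two
  components are eligible by default (configurable).
* A flat ECG, all-zero source patterns, all-channels-dropped rejection,
  zero retained trials, zero-variance t tests, and IR with a zero
  denominator are all explicit errors, not silent results.
* The exact sign-flip enumeration threshold ($2^n \le 4096$) makes small-n
  cluster p values reproducible to machine precision.
* At realistic single-trial SNR, component selection needs a few hundred
  trials to be reliable (real sessions of this kind collect 2000 per
  condition); with too few trials the leading canonical components can be
  noise-dominated and `select_component()` refuses with diagnostics rather
  than silently returning a noise component.

## Problem sizes used in the checks

The bundled tests and `scripts/acceptance.R` run on synthetic sessions of
roughly 100–1000 trials and 150–600 s at 1 kHz, 500-replicate null
simulations for the family-wise error rate, 1000-replicate robustness
cells, and 20-seed pattern-recovery sweeps — sizes chosen so the whole
verification runs on a laptop in minutes while keeping Monte-Carlo error
well inside each stated tolerance.

## Known limitations

Ocular/muscle ICA cleanup is exposed only as a hook (any function mapping a
recording to a recording can be slotted between stages); mixed-effects
models of cross-level covariation are left to standard mixed-model
software; the signal-space-projection variant of cardiac cleanup is
documented as an alternative but not implemented; and automated component
selection beyond the latency/focality heuristic remains future work, as it
does for the field.
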