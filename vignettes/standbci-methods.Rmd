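---
title: "Decoding sit-to-stand motor imagery: models, synthetic data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sit-to-stand motor imagery: models, synthetic data and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `standbci`, what the
synthetic session generator does and does not emulate, and the numerical and
design decisions a maintainer would want spelled out. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute
themselves.

## The decoding problem

A binary motor-imagery brain–computer interface must decide, from a short
multichannel EEG segment, whether the user is imagining a posture transition
(sit-to-stand or stand-to-sit) or is idle. The physiological signature is
event-related desynchronization (ERD): imagining the movement attenuates the
sensorimotor alpha (8–12 Hz) and beta rhythms over central and
centro-parietal cortex, followed by a beta rebound (ERS). The decoding chain
is classical: band-limited spatial filtering (filter-bank CSP) turns the
spatial covariance difference between classes into a low-dimensional
log-variance feature vector, and a linear discriminant with shrinkage
covariances classifies it.

## Trial protocol and data model

A session consists of trials with four stages: fixation (4 s), action
observation (3 s), imagery or idle (4 s offline; up to 15 s online), rest
(4 s). An offline dataset holds 45 motor-imagery and 45 idle trials. The
continuous recording is a channels × samples matrix in microvolts at 250 Hz
over 17 electrodes of the 10–20 system around the motor cortex (F3…P4,
reference right earlobe, ground AFz), with events in a sidecar table.

Sessions are exchanged as EDF (16-bit, physical range ±2000 µV, quantization
step ≈ 0.061 µV) plus a tab-separated event file; EDF+ annotations are
deliberately avoided as dialect-prone.

## The synthetic session generator

No recorded EEG ships with the package; every stage is exercised against
`simulate_session()`. The generator emulates:

* two shared sensorimotor sources — amplitude-modulated narrowband noise in
  8–12 Hz (alpha, 6 µV at unit-weight channels) and 16–24 Hz (beta, 3 µV) —
  mixed to the montage through a fixed central/centro-parietal topography
  (weight 1 at C3/Cz/C4, 0.8 at CP1/CP2, decaying outward). Narrowband
  *noise* rather than sinusoids is essential: pure tones make spatial
  covariances rank-deficient, which CSP cannot digest;
* per-channel unstructured background rhythms (2 µV) and 1/f pink noise
  (6 µV), so channels are never collinear;
* class-dependent ERD: on motor-imagery trials the source amplitudes are
  attenuated by `erd_depth` (default 0.5) with a 0.5-s raised-cosine ramp,
  and beta rebounds to `1 + ers_gain` (default 1.3×) in the final imagery
  second;
* injectable artifacts with per-trial probabilities: frontal blink
  deflections (300–600 µV), rail-clipping plateaus, and 20–40 Hz EMG bursts,
  all placed inside the epoching window and logged so that rejection can be
  validated against ground truth.

**Timing of the ERD ramp.** The class-dependent attenuation begins 1 s
*before* the imagery cue (`erd_onset = -1`). In this cued protocol the
subject already knows the upcoming task during action observation, and
preparatory desynchronization before the executive cue is the expected
physiology; it is also what makes the pre-cue `[-1, 0)` s analysis window
informative, which the two-window feature design presumes. Setting
`erd_onset = 0` yields sessions where only the post-cue window discriminates.

**What passing tests do and do not show.** The generator produces Gaussian,
stationary-by-segment, linearly mixed sources with a fixed topography. Real
EEG adds non-stationary rhythms, inter-subject topography variation,
volume-conduction spectra, eye movements correlated with task, and slow
drifts. Tests passing on this generator validate the *pipeline mechanics*
(geometry, leakage-free evaluation, calibration of statistical procedures,
detection timing) — they do not certify any particular accuracy on recorded
EEG. The generator's defaults (`erd_depth = 0.5` etc.) are free parameters
of the simulation, not empirical claims.

## Preprocessing

Epochs are `[-1, +1)` s around the imagery marker (half-open, 0-based
sample indexing; onset sample belongs to the second window). Artifact
statistics follow the three-criterion rule: peak-to-peak > 200 µV, standard
deviation > 50 µV (both on the 4–40 Hz signal, per epoch), or 20–40/4–40 Hz
power ratio > 0.7, each evaluated per channel; an epoch is discarded when
any channel violates any criterion (strict inequalities). A channel with
zero 4–40 Hz energy makes the ratio undefined and flags the epoch rather
than propagating NaN. Flagged epochs are auto-discarded — the original
protocol added a human visual double-check, which a library cannot
reproduce; the violation report preserves auditability instead.

FIR filters are windowed-sinc (Hamming) of order `fs` (a 1-s kernel,
transition ≈ 2 Hz), applied with group-delay compensation so filtered epochs
stay aligned. The acquisition-chain model (0.01–60 Hz, 6th-order
Butterworth) is realized as cascaded analog-prototype biquads applied
forward–backward: at 250 Hz the 0.01 Hz edge has a normalized cutoff of
8 × 10⁻⁵ and a direct transfer-function realization is numerically
degenerate, while second-order sections remain well conditioned.

## FBCSP

Band kernels are frequency-domain Gaussians with unit peak gain, standard
deviation (high − low)/2, centered at the band midpoint — "unitary gain"
read as unit *peak* gain so in-band amplitudes are preserved. Per-epoch
covariances are trace-normalized (`XX'/tr(XX')`) and averaged per class;
CSP whitens the composite covariance (with a 10⁻¹⁰·trace ridge) and
diagonalizes the class-1 covariance in the whitened space, so
`W (C1+C2) W' = I` and eigenvalues lie in [0, 1]. Ties in the eigen-sort
keep the original order and each filter's sign is fixed so its
largest-magnitude coefficient is positive, making fits reproducible. Six
filters (first/last three) are retained; features are the plain
log-variances of the projections (not the normalized log-power fraction of
other FBCSP variants), ordered band-major. Fisher scores are descriptive
only — all 30 features enter the classifier.

## Regularized LDA

Class covariances use the Ledoit–Wolf optimal-shrinkage estimator
(sample covariance with denominator *n*, target `tr(S)/p · I`). The
discriminant is the pooled-covariance Gaussian Bayes rule. The published
per-class-inverse forms of the weight and bias do not reduce to a
consistent linear rule as printed; the pooled form is the standard reading
and is what the package implements and tests (equivalence with a
brute-force Gaussian Bayes oracle). Two numerical notes:

* at exactly *n* = 2 observations the Ledoit–Wolf intensity degenerates to
  0 (both centered samples give the same outer product), so at least three
  observations per class are needed for meaningful shrinkage;
* predictions are exactly equivariant under orthogonal × scalar feature
  maps plus shifts, but not under arbitrary affine maps, because the
  shrinkage target is a scaled identity.

A decision value of exactly 0 maps to the idle class, biasing an online
system away from false activations.

## Offline evaluation

Cross-validation splits at the *trial* level (both windows of a trial share
a fold; window-level splitting would leak within-trial correlation), with
fold sizes differing by at most one and the CSP bank and classifier refit
inside every training split. Accuracies follow the per-class
`n_correct/n_total` convention, pooled over folds. The permutation test
shuffles trial labels, repeats the whole cross-validation per permutation,
and uses the add-one estimator `p = (1 + #{null ≥ obs}) / (1 + n_perm)`,
which can never return 0. The package default is 1000 permutations; the
test suite and examples use 49–199 permutations and 10–45 trials per class
to keep runtimes in seconds-to-minutes, sizes chosen as the smallest at
which the statistical checks are stable.

## Online engine

Timing contract: the first 1-s epoch is acquired over second one, its five
50-sample windows are classified over second two (labels at 1.2 … 2.0 s),
and a fired decision is emitted after a 1-s selection delay — the earliest
emission is 3.0 s and a trial gives up at 15 s. The five 50-sample
segments are contiguous sub-windows of each epoch: five of them exactly
tile the 250-sample epoch, which is the consistent reading of the
protocol; a true sliding mode (1-s windows advancing by 50 samples) is
exposed as a config option but is not the default. Band-pass filtering is
applied to the whole 1-s epoch before sub-windowing because 50 samples
cannot support a 4 Hz filter. The label buffer spans epoch boundaries
(oldest labels are dismissed). Replay is pure: simulated time advances by
sample count, so replays are bit-reproducible. Timed-out trials count as
misdetections of the cued class and are excluded from the mean detection
time (only detected trials have one).

## ERSP

Full-trial epochs (`[-7, 4)` s) are decomposed with complex Morlet
wavelets, cycles rising linearly from 7 at 4 Hz to 14 at 30 Hz, on a
200-point time grid that excludes 3.5 standard deviations of the widest
wavelet at both edges (≈ (−6.03, 3.03) s). Power is normalized to the
(−3.5, −3) s baseline in dB (the EEGLAB convention), so ERD is negative.

Significance uses a bootstrap with two deliberate choices. First,
replicates resample *trials* (with replacement) as well as baseline time
points: the 0.5-s baseline is shorter than the wavelet autocorrelation
time, so its within-trial samples are nearly collinear and resampling time
points alone collapses the null variance. Second, the tested statistic is
the deviation of each cell's trial-averaged power from the baseline mean,
and the null is the difference of two independent bootstrap means — the
baseline mean itself is estimated from few effective samples and its
sampling error is as large as that of any tested cell. Calibration holds
on average over datasets; the per-dataset masked fraction scatters widely
because all cells of a dataset share one baseline realization. No
multiple-comparison correction is applied. The resting stage is excluded
from the decomposition input.

## Known limitations

* The generator's fixed topography and Gaussian sources understate the
  variability of real EEG; accuracies on simulated sessions are not
  forecasts for recorded data.
* The blink artifact is sharpened (150 ms) so that its band-passed residual
  reliably exceeds the peak-to-peak criterion; physiological blinks are
  slower and are partially suppressed by the 4 Hz high-pass, so real blink
  rejection leans more on the unfiltered deflection than this model does.
* The ERSP bootstrap is slightly conservative for cells temporally close to
  the baseline (their estimates co-vary with the baseline mean).
* The online engine assumes a fixed 250-sample epoch and 5 labels/s; other
  rates require consistent `online_config()` geometry.
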