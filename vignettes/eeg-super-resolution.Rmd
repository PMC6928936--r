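---
title: "Spatial super-resolution of EEG: model, simulation design and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial super-resolution of EEG: model, simulation design and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

High-density EEG montages resolve scalp topography and support source
localization far better than the sparse montages that are practical in
mobile, clinical or consumer settings.  `eegsr` studies a data-driven remedy:
record a dense (64-channel) montage once, then train a convolutional network
that maps interpolated sparse-montage recordings ("LR", low resolution) back
to the dense montage ("SR", super resolution).  The package contains the
whole experimental apparatus needed to study this idea without any recorded
data: a spherical-head forward model and trial simulator, channel
subsampling and interpolation, the network and its training loop, a
beamformer for source-level scoring, and sensor-level metrics.

This vignette explains the science behind each stage, the defaults and why
they were chosen, and what the accompanying tests do and do not show.

## 1. Forward model: dipoles in a three-shell sphere

Scalp potentials are computed for current dipoles inside a volume conductor
of three concentric spheres (brain, skull, scalp) with relative radii
0.87 / 0.92 / 1 and relative conductivities 1 / 0.0125 / 1 — the classical
poorly-conducting-skull model.  On spherical geometry the boundary-value
problem has an exact spherical-harmonic series solution, so the package
implements that series rather than a numerical boundary-element scheme: per
harmonic degree $n$ the radial coefficients of the three shells satisfy a
5-equation linear system (continuity of potential and of radial current at
the two interfaces, zero current through the scalp), giving a surface
transfer coefficient $g_n$; the sensor potential of a dipole with radial
moment $m_r$ and tangential moment $m_t$ at radius $b$ is

$$ V = \frac{1}{4\pi\sigma_1}\sum_{n\ge1} g_n\, b^{\,n-1}\left[ n\, m_r P_n(\cos\gamma) + m_t P_n'(\cos\gamma)\,(\hat s\cdot \hat t)\right], $$

average-referenced over the montage.  For equal conductivities $g_n$
collapses to the homogeneous-sphere value $(2n+1)/n$, which is the oracle
the test suite checks against (relative error $<10^{-6}$ at truncation
order 100, the default; the series converges geometrically in $b^n$).
Electrode positions are an idealized spherical 10-10 layout with the 64
labels of the Biosemi ActiveTwo system, stored as a plain-text `.sfp` file
and projected onto the unit sphere on load.

A physical scale is only needed for metric quantities (grid spacing,
localization error); the default scalp radius is 100 mm, so the brain shell
has radius 87 mm.

## 2. Simulated trials and noise

The default simulation drives two dipoles, one per hemisphere, at
$(\pm 0.62, 0, 0.48)$ (radius 0.78 — a typical cortical depth inside the
0.87 brain shell), with exactly tangential orientations and
amplitude-modulated 8 Hz and 12 Hz waveforms with distinct envelopes.  Every
trial is 1 s at 512 Hz and identical before noise.  Superficial tangential
sources were chosen deliberately: their scalp patterns are focal, so sparse
montages undersample them and the interpolation baseline is imperfect —
the regime in which super-resolution is interesting.  (Deeper sources make
interpolation nearly perfect and the comparison trivial; the true source
configuration of the reference study is only shown graphically, so this
choice is the package's own.)

The clean signal is normalized to unit mean-square power over all samples
and channels.  Noise is added per trial (independent realizations) and
scaled so the empirical power ratio $P_\text{clean}/P_\text{noise}$ over the
whole array equals the requested SNR exactly; with unit signal power the
sensor MSE of noisy HR data against the noiseless signal is $1/\mathrm{SNR}$
by construction, which anchors the SNR scale.  The SNR grid of the study is
$\{100, 50, 10, 5, 1, 0.5, 0.1, 0.05, 0.01\}$.  Two noise kinds exist:
white Gaussian, and a "brain noise" surrogate with $1/f^\alpha$ spectrum
(default $\alpha = 1$, low-frequency dominant, optionally spatially mixed by
a blended random orthogonal matrix).  A recorded resting-state noise file
is not distributable, so the surrogate reproduces the property that matters
for the study — low-frequency dominance — but not the true spatial
covariance of brain noise; conclusions about real recordings should be
drawn with that limitation in mind.

## 3. Down-scaling and the interpolation baseline

The 64-channel montage is reduced to declared subsets of 32, 16, 8 or 4
channels (the 32- and 16-channel sets follow the corresponding Biosemi caps;
the 8-channel set covers the head evenly; the 4-channel set sits on the
central strip and deliberately leaves the boundary uncovered).  The LR
baseline — and the network input — is produced by inverse
geodesic-distance-weighted interpolation: each missing channel is the
weighted average of its 4 nearest retained electrodes (3 for the 4-channel
subset), weights normalized to sum to one.  The scheme is parameter-free,
linear, and a convex combination, three properties the test suite asserts;
retained channels pass through bit-exactly.  Spherical-spline or
surface-Laplacian interpolation are deliberately out of scope — the point of
the baseline is simplicity.

## 4. The super-resolution network

The network treats an epoch as a time-by-channel image with one feature
channel and applies

* encoder: three convolutions, kernels 13 x 5 (time x channel), 64 filters,
  stride 2 on both axes;
* decoder: three transposed convolutions, kernels 13 x 9, 64 filters,
  stride-2 upsampling;
* integration: one 13 x 5 / 64-filter convolution and one 7 x 1 / 1-filter
  convolution, both stride 1, which also suppress the checkerboard pattern
  that strided transposed convolutions otherwise imprint.

All activations are linear ($y = x$).  That is not an accident: EEG
amplitudes are signed and unbounded, so rectifiers and saturating
nonlinearities discard or compress half of the signal range; with a linear
network the model class is exactly the set of (convolutionally structured)
linear operators, and training still works because the factorized
parametrization is what the optimizer navigates.  With biases zeroed the
trained network is a verifiable linear operator — a property test asserts
additivity and homogeneity.

Weights use He initialisation; training minimises elementwise mean squared
error with Adam (learning rate $5\times10^{-4}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$).  Training runs for a fixed number of epochs — the
stopping criterion of the study — keyed by SNR: 40 (SNR 100, 50), 80
(SNR 10, 5), 150 (SNR 1), 200 (SNR 0.5, 0.1), 500 (SNR 0.05, 0.01), and 300
for evoked-potential-like data.  Validation MSE is recorded each epoch but
never stops training.  Since the counts are far too small to be minibatch
steps over hundreds of trials, "iteration" is read as epoch (one full pass);
the default batch size is 32, a documented choice the study leaves open.

Implementation notes.  Convolutions run in single precision through BLAS
`sgemm` (C++ backend); a transposed convolution is computed as the exact
adjoint of the mirrored strided convolution, which the tests verify against
inner-product identities and numerical directional derivatives.  "Same"
zero padding is used everywhere; inputs whose time length is not a multiple
of 8 (e.g. 666-sample evoked epochs) are reflection-padded before the
encoder and cropped to the original length in the integration stage, with
the padded samples carrying no loss.  Trial shuffling and initialisation
derive from one seed, and training is bit-reproducible on a single thread.

Data splits follow the study protocol: 64 % / 16 % / 20 %
train/validation/test (1000 trials give 640/160/200, 932 give 596/150/186 —
train and test floored, validation the remainder), repeated five times for
cross-validation where configured.

## 5. Source-level scoring: array-gain minimum-variance beamformer

Source maps are computed on a regular 5 mm lattice restricted to the brain
shell (about 22,000 voxels at the default radii; the voxel count is a
function of the configured radii and spacing).  For each voxel the three
leadfield columns are normalized to unit norm (the array-gain constraint)
and the beamformer power is

$$ P(v) = \max_{\|u\|=1} \frac{1}{u^\top \tilde L(v)^\top C^{-1} \tilde L(v)\, u} = \frac{1}{\lambda_{\min}\left(\tilde L(v)^\top C^{-1} \tilde L(v)\right)}, $$

with $C$ the sensor covariance over the scoring window (the whole 1 s trial
for simulated single trials; the N1-P2 window for evoked data), stabilized
by diagonal loading $10^{-3}\,\mathrm{tr}(C)/64$ — single-trial covariances
(512 samples, 64 channels) need it.  Maps are normalized to maximum 1,
thresholded (0.3 for simulated data, 0.1 for evoked data — both visibility
thresholds from the reference study), and peaks are local maxima over the
26-neighbourhood within the active set, merged below a 20 mm separation.
"Correct detection" means every true source has a peak within 20 mm and no
spurious peak remains — the matching radius is the package's documented
choice.  Beamformer power is invariant to global covariance scaling, and a
noiseless dipole at least 10 mm inside the brain surface localizes to
within one grid step; both are asserted in the tests.

## 6. Sensor metrics and the evoked-potential generator

Sensor-level scoring uses per-trial MSE (mean over time, averaged over
channels — the per-channel breakdown is exposed too) and the Pearson
correlation with time and channel samples pooled per trial.  Evoked
components are scored on trial averages: N1 is the most negative sample in
a 40–110 ms window, P2 the most positive in 110–220 ms (windows bracket the
latencies reported for auditory responses and are configurable); amplitude
errors and latency errors sum absolute differences over both components.
Pointwise comparisons between conditions use a paired t-test per
time-sample and channel after keeping every 8th sample, uncorrected at
$p < 0.01$ by design — mirroring the exploratory use in the study, not a
recommendation for confirmatory analysis.

The synthetic evoked generator emulates the recording protocol that the
study's experimental arm used: 932 usable trials of 666 samples at 512 Hz
spanning −300 to 1000 ms.  Two dipoles at bilateral temporal positions
drive a biphasic waveform (negative Gaussian lobe at 70 ms, sigma 15 ms;
positive lobe at 140 ms, sigma 25 ms) with per-trial latency jitter (3 ms)
and log-normal amplitude jitter; the pre-stimulus interval contains only
noise.  The $1/f$ noise is scaled so the estimated SNR — post-stimulus
power over pre-stimulus power — is 1.2, the value estimated for the real
recordings.  The generator returns its ground truth (dipole positions,
per-trial jitters), which is what the latency-recovery and
source-recovery tests score against.  It does not model inter-subject
variability, ocular or muscular artifacts, or the ISI structure of the
experiment.

## 7. Numerical and design choices worth knowing

* **Forward series truncation** defaults to 100 terms; the equal-conductivity
  oracle bounds the truncation error at $10^{-6}$ for sources up to
  cortical depth.
* **Eq-style localization error** is implemented as the Euclidean norm
  between maximum-power voxels (the printed formula's exponent placement is
  read as a typo), matched greedily from the strongest reference peak.
* **Amplitude error** compares maximum normalized power inside 20 mm
  regions of interest around the reference sources, averaged over sources;
  maps are re-normalized before comparison so a uniform scaling is
  invisible, as it should be for normalized beamformer output.
* **Focality** is the reciprocal active-voxel count, so its value depends on
  the grid spacing; comparisons are only meaningful at a fixed grid.
* **Degenerate cases** are defined, not guessed: a flat signal yields a
  zero-amplitude component at the window start; zero within-pair variance
  makes a time point "not significant"; an empty active set is an error for
  focality rather than infinity.
* **Transposed-convolution output size** (stride 2 admits two sizes) is
  fixed to exactly double the input, the variant whose adjoint is the
  "same"-padded strided convolution.

## 8. Problem sizes used by the shipped tests and acceptance script

The study's training protocol (640 trials for 80 epochs at SNR 5) is a
GPU-scale computation.  The package's own runs are sized for a single CPU:
the acceptance script trains on 48 trials for 12 epochs with batch size 4
(144 gradient steps; very small batches were avoided because Adam's
late-training steps become oscillatory there), evaluates LR metrics on all
200 held-out test trials and SR metrics on 48 of them, and beamforms 24 SR
trials on the full 5 mm grid.  The test suite uses smaller configurations
again.  These
sizes are stated here because they are part of the reported numbers: with
more training data and the full epoch schedule the SR error keeps
decreasing, so the shipped configuration is a conservative estimate of what
the method achieves.  What the passing tests show is that every component
is correct against independent oracles and that the headline ordering
(SR better than interpolated LR at the sensor level, SR recovering both
sources where interpolated LR recovers none) emerges already at desk scale;
they do not show subject-level generalization on real recordings, which
requires data the package deliberately does not ship.

## 9. Worked example

```{r, eval = FALSE}
library(eegsr)
montage <- build_montage()
head <- head_model()

clean <- simulate_clean_trials(default_dipoles(head = head), montage, head,
                               n_trials = 120)
hr <- add_noise(clean, snr = 5, seed = 1)
lr <- interpolate_lr(select_channels(hr, montage, 16), montage)

split <- split_trials(120, n_repeats = 1, seed = 1)[[1]]
fit <- sr_fit(epoch_subset(lr, split$train), epoch_subset(hr, split$train),
              epochs = 12, batch_size = 2, seed = 1)
sr <- predict(fit, epoch_subset(lr, split$test))

mean(mse_epochs(epoch_subset(clean, split$test), epoch_subset(lr, split$test)))
mean(mse_epochs(epoch_subset(clean, split$test), sr))
plot(fit)
```
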