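---
title: "Methods: muscle-strength assessment from sEMG and IMU recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle-strength assessment from sEMG and IMU recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strengthsense)
```

## The assessment problem

Manual muscle testing (MMT) grades shoulder strength on an ordinal 0--5
scale by clinician judgement. `strengthsense` implements a quantitative
counterpart for the shoulder-flexion task: three-channel surface EMG over
the anterior, middle and posterior deltoid (nominally 10 kHz) and an
arm-mounted six-axis IMU (100 Hz) are reduced to 21 features per trial, and
regression models map those features to the MMT grade (grades 2--5; grades
0--1 produce no usable voluntary signal). Four regressors are compared: a
backpropagation neural network (BPNN), epsilon-insensitive support vector
regression (SVR), and both with particle-swarm-optimized (PSO)
hyperparameters or weights (PSO-BPNN, PSO-SVR).

## Signal model and preprocessing

Raw sEMG is denoised with a Savitzky--Golay filter (window 51 samples,
cubic polynomials): each output sample is the centre value of a
least-squares cubic fitted to its window. The filter preserves burst
morphology (any polynomial of degree at most 3 passes through unchanged)
while attenuating high-frequency noise. The window is mirror-padded by 25
samples on each side so output length equals input length; the mirror pad
avoids the edge blow-up of polynomial extrapolation. Note the window is
specified in samples: at the 2 kHz desk-scale rate used in the test suite it
spans 25.5 ms and is a considerably stronger smoother than at 10 kHz, which
attenuates part of the 20--450 Hz sEMG band; relative amplitude relations
between channels and trials are preserved by linearity, so the extracted
features remain informative at either rate.

Channel quality control mirrors the acquisition-time exclusion rules and is
report-only at library level (`qc_channels()`): baseline instability is the
range of a 1 Hz low-pass trend (computed on a ~100 Hz bin-averaged copy for
numerical stability of the low-cutoff Butterworth filter), and powerline
contamination is the fraction of Welch spectral power within 1 Hz of the
mains frequency (default 50 Hz, switchable to 60 Hz). The defaults -- drift
below 20% of channel RMS, powerline fraction below 0.2 -- are artifact
choices exposed in the configuration; the full pipeline excludes trials
with any failing channel.

## sEMG features

Per channel, over the full aligned trial window (one scalar per feature per
channel per trial):

* RMS $= \sqrt{\tfrac1N \sum_i x_i^2}$ -- signal energy;
* MAV $= \tfrac1N \sum_i |x_i|$ -- rectified mean amplitude;
* iEMG $= \tfrac1{f_s}\sum_i |x_i|$ -- rectangular-rule integral of the
  rectified signal (amplitude-seconds), so iEMG $=$ MAV $\times$ duration
  by construction;
* MF -- the median frequency, i.e. the frequency splitting the power
  spectrum into equal-power halves.

The PSD behind MF is a Welch estimate: Hann-tapered segments of
`min(N, 4096)` samples with 50% overlap. The half-power crossing is
interpolated on the cumulative spectrum with each bin's mass centred on its
bin frequency; with the cruder edge-based cumulative, a pure tone's mass
(split across two bins) biases the crossing by up to one bin width, while
the midpoint convention recovers a 50 Hz tone to within 0.01 Hz at a 2.44 Hz
bin width. RMS, MAV and iEMG scale linearly with amplitude and MF is
amplitude-invariant; the suite property-tests these equivariances together
with RMS $\ge$ MAV.

## Orientation fusion

Accelerometer inclination uses the gravity-projection model
(`roll = atan2(a_y, a_z)`, `pitch = atan2(-a_x, sqrt(a_y^2 + a_z^2))`,
X axis anterior). The complementary filter blends, per step,

$$\mathrm{roll}_t = K\,(\mathrm{roll}_{t-1} + \omega_x \Delta t) + (1-K)\,\mathrm{roll}^{acc}_t,$$

likewise for pitch with $\omega_y$, while yaw -- unobservable from gravity
-- is pure gyro integration. The gyro term propagates the previous *fused*
estimate: an independent pure-gyro integrator drifts without bound and
would defeat the blend. $K = 0.4$ (dimensionless, in $[0,1]$) balances
short-term gyro responsiveness against long-term accelerometer stability;
$K = 0$ returns accelerometer angles, $K = 1$ pure integration, and both
limits are asserted in the suite. No gyro bias is estimated (trials last
seconds). Each of the nine IMU channels is reduced to its peak absolute
value (peak absolute excursion from the initial angle, for the Euler
channels) -- strength relates to peak kinematics; mean and range reductions
are available. Device-reported Euler angles, when present on disk, can be
used verbatim via `use_device_angles`; the default re-fuses from raw
streams for reproducibility.

## Dataset, normalization, splitting

The feature table has 21 columns: 3 muscles $\times$ {RMS, iEMG, MAV, MF}
plus the 9 IMU scalars -- the only decomposition consistent with both the
feature list and the count. Features are min--max normalized,
$x' = (x - \min)/(\max - \min)$; the state is fitted on the training
partition only and applied to test data (fitting on all rows leaks
information; `norm_on_all = TRUE` reproduces the looser convention).
Labels are never normalized. The 7:3 split takes `floor(0.7 n)` training
rows (101 of 145) from a seeded shuffle; splitting is by trial, mirroring
the pooled design, with a group-aware option because trial-level splitting
of repeated measures inflates apparent performance. Five-fold
cross-validation partitions are disjoint and exhaustive (145 rows give five
folds of 29).

## Particle swarm optimizer

Velocity update
$v \leftarrow \omega v + c_1 r_1 (pbest - x) + c_2 r_2 (gbest - x)$ with
$r_1, r_2 \sim U(0,1)$ drawn per particle per dimension, followed by the
canonical position update $x \leftarrow x + v$ (the position rule is the
standard one; only the velocity rule is prescribed). Positions are clipped
to the search box and velocities clamped to $\pm(hi - lo)$: the PSO-BPNN
setting $c_1 = c_2 = 4.494$ exceeds the classical stability bound
($c_1 + c_2 \le 4$) and diverges without clamping, so clamping is the
minimal stabilizer. Inertia defaults to $\omega = 0.7$ (inside the
practical 0.4--0.9 range; the exact value is not prescribed) and is
config-exposed. Minimization convention throughout; candidates with
non-finite fitness are rejected without touching `pbest`. The per-iteration
`gbest` trace is returned for convergence plots and is non-increasing by
construction.

## Models

* **BPNN** -- one hidden layer of 5 tanh units, linear output, full-batch
  gradient descent on squared error for up to 1000 epochs, learning rate
  0.01 (tanh and plain gradient descent are the package's choices; only
  layer width and epoch budget are prescribed). Targets are centred
  internally. The descent is monitored: a loss-increasing step is reverted
  with the rate halved, so training error never increases.
* **SVR** -- RBF kernel, $C = 10$, $\gamma = 0.1$, $\epsilon = 0.1$;
  residuals inside the $\epsilon$-tube incur no loss. When the whole target
  range fits inside the tube the exact optimum is the flat mid-range
  function with zero slack, handled explicitly. The quadratic program is
  solved by libsvm (via e1071) at a tightened convergence tolerance
  ($10^{-6}$) so solutions match an independent dual-QP solver to $10^{-4}$.
* **PSO-SVR** -- the swarm (10 particles, 100 iterations,
  $c_1 = c_2 = 1.7$) searches $C \in [1, 100]$, $\gamma \in [0.001, 1]$
  minimizing five-fold cross-validated RMSE on the training partition, and
  the final model is refit at the best parameters. Raw training RMSE is
  available as the fitness (`fitness = "train"`) but drives $C$ to its
  bound and overfits, so CV is the default. The tube half-width is excluded
  from the search by default (the tuned set is the kernel and penalty
  parameters) and can be included by flag. The reference configuration is
  evaluated under the same fitness and kept if it beats the swarm best, so
  tuning never returns a model worse than the default.
* **PSO-BPNN** -- the swarm (5 particles, 100 iterations,
  $c_1 = c_2 = 4.494$) searches the flattened weight-and-bias vector
  minimizing training MSE, then backpropagation fine-tunes from the swarm
  best. The search box is the per-layer weight-initialization region
  (input weights scaled by fan-in: $\pm 0.5/\sqrt{d}$, hidden biases
  $\pm 0.5$, output weights $\pm 0.5/\sqrt{h}$): a box that ignores fan-in
  puts the swarm best in tanh-saturated corners from which gradient descent
  cannot recover, which defeats the global-then-local design.

All four trainers are seed-deterministic end to end.

## Evaluation harness and statistics

`regression_metrics()` computes $R^2$, RMSE, MAE and MBE
$= \mathrm{mean}(\text{actual} - \text{predicted})$. Under this sign
convention a *negative* MBE means over-prediction; the opposite
textual convention exists, so `flip_mbe_sign` is provided. The identities
RMSE $\ge$ MAE $\ge$ |MBE| are property-tested.

`run_experiment()` repeats, per model: fresh seeded 7:3 split, training,
test metrics; summaries are mean $\pm$ SD over repeats (SDs are taken over
repeats; over folds is the other defensible reading). Per-repeat seeds fan
out from one master seed (`seed + 7919 * r`), making the whole report a
pure function of the master seed. `compare_models()` runs a one-way
repeated-measures ANOVA per metric, built from sums of squares first
principles (models = within factor, repeats = subjects; no sphericity
correction) and verified in the suite against `aov()` and against the
$F = t^2$ identity for two models; pairwise paired t-tests are
Bonferroni-corrected ($\times k(k-1)/2$, capped at 1) and 95% Student-t
intervals accompany each model mean. Degenerate cases (identical metric
columns) return $F = 0$, $p = 1$ rather than 0/0.

## The synthetic-study generator

No recordings are distributable, so the generator emulates the study
design: 15 subjects $\times$ 10 trials, grades 2--5, 5 of 150 trials
flagged unusable, leaving 145. Grade enters through three monotone maps
chosen once as physiologically plausible stylizations:

* sEMG amplitude gain 0.5 / 1.0 / 1.6 / 2.3 (arbitrary units) -- stronger
  contractions recruit more motor units;
* spectral centre 85 / 95 / 105 / 115 Hz -- recruitment shifts spectral
  mass upward;
* peak flexion angle 25 / 50 / 70 / 85 degrees -- weaker grades cannot
  complete the range against gravity. Peaks are capped at 88 degrees
  because at 90 degrees pitch the gravity vector carries no roll
  information and accelerometer tilt folds back; the generator stays inside
  the observable range.

sEMG is unit-RMS band-limited Gaussian noise (Butterworth band of
$\pm 60$ Hz around the grade's centre, inside 20--450 Hz), modulated by a
smooth flexion envelope and scaled by gain, a per-subject lognormal effect
(SD 0.15) and a per-muscle weight (1 / 0.7 / 0.4 anterior to posterior).
The IMU follows a minimum-jerk rise-and-return pitch trajectory with
analytic rates, gravity-projected accelerometer samples (noise SD 0.03 g),
gyro noise SD 1 deg/s, and a small yaw oscillation so the yaw feature is
not degenerate in a sagittal task. With noise set to zero the
accelerometer angles recover the pitch trajectory exactly and the fused
pitch tracks it within 2 degrees after the transient -- the suite's
round-trip check.

What the generator does **not** model: motor-unit action potentials,
co-contraction, spasticity, electrode artifacts, label noise from
inter-rater disagreement. Passing tests therefore demonstrate pipeline
correctness and recoverability of a grade-dependent signal, not clinical
performance; on this deliberately learnable synthetic signal all four
models reach test $R^2$ well above what heterogeneous human data yields,
and only the model *ordering* (tuned $\ge$ untuned) is read as the
meaningful mirror of the real study.

## Problem sizes and numerical choices

The suite and the acceptance script run the study at 2 kHz sEMG (the
band-limited signal is fully represented; 1--2 kHz satisfies Nyquist for
the 20--450 Hz band), 3 s trials, 10-repeat experiments, and PSO budgets as
prescribed (10 $\times$ 100 for SVR tuning with 5-fold CV fitness,
5 $\times$ 100 for weight search). Labels are treated as continuous
regression targets exactly as in the assessment protocol (an acknowledged
approximation for an ordinal scale). Ties and degenerate inputs: constant
feature columns normalize to 0 with a warning; constant targets yield flat
predictors; all-zero signals make MF undefined and raise an error rather
than returning a silent 0.

## Known limitations

* The amplitude scale of real sEMG hardware (ADC counts, gain) is not
  modelled; all amplitudes are arbitrary units, which the features tolerate
  by scale equivariance.
* Trial-level 7:3 splitting mixes subjects across partitions; the
  group-aware split exists precisely because the pooled protocol is
  optimistic for subject-level generalization.
* The complementary filter estimates Euler angles only; near 90 degrees of
  pitch the accelerometer loses roll observability (the generator avoids
  the region; real overhead movements would need a quaternion filter).
* RM-ANOVA is applied without sphericity correction.
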