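---
title: "Synergy-space recurrent decoding of forearm motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synergy-space recurrent decoding of forearm motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synspace)
```

## The problem

After a transhumeral amputation the user retains shoulder motion but no
elbow or forearm. A residual-limb control strategy estimates the missing
distal joints — elbow flexion–extension (`FA_y`) and forearm
pronation–supination (`FA_x`) — from the three recorded shoulder orientation
angles (`SH_x` internal–external rotation, `SH_y` flexion–extension, `SH_z`
abduction–adduction) and, optionally, their angular velocities.

`synspace` implements a synergy-space decoder for this task. During planar
reaching, the five joint angles covary in a small number of fixed spatial
patterns ("kinematic synergies"). Writing the preprocessed training data as
a channels-by-time matrix $X$, the spatial synergy model is the low-rank
factorization

$$X \approx W\,C,$$

where the columns of $W$ are the synergy loading vectors (constant ratios
across degrees of freedom) and the rows of $C$ are their time-varying
activation signals. $W$ and $C$ are obtained by principal component
analysis, which minimizes the Frobenius reconstruction error
$\lVert X - WC \rVert_F$ at any fixed rank. A windowed recurrent network
(stacked LSTM) is then trained to predict the activation signals from
shoulder kinematics; predicted activations are pushed back through $W$
(restricted to the forearm rows) and denormalized to produce forearm angle
estimates in degrees. Three learning methodologies are compared throughout:

* **two-synergy** — decompose all 5 channels, predict the first two
  activation signals, reconstruct the forearm rows;
* **one-synergy** — decompose the 2 forearm channels alone, predict the
  single dominant activation;
* **direct** — regress normalized forearm angles on shoulder kinematics
  with no decomposition.

## Preprocessing chain

A recorded session is a continuous 5-channel stream at 120 Hz with rest
periods between reaching movements. The pipeline (`prepare_subject()`) is:

1. **Segmentation** (`segment_trials()`). The channels are low-pass
   filtered at 3 Hz, differentiated, and combined into one smoothed
   aggregate speed trace. A movement starts where this trace exceeds a
   threshold for at least 100 ms and ends at the symmetric condition;
   sub-threshold dips shorter than 100 ms (the zero-velocity instant at the
   reach turnaround) are merged. The threshold sits `speed_threshold`
   (default 5%) of the way from the rest-level speed — the 10th percentile
   of the trace, zero for noise-free data — to its peak; a pure
   fraction-of-peak rule was found to fall below the noise floor of the
   speed trace once per-sample angle noise reaches 1–2°. A candidate
   segment must additionally reach 25% of the rest-to-peak range
   (`prominence`), which rejects slow noise excursions that linger above
   the onset threshold, and interior sub-threshold dips shorter than
   `merge_gap` (300 ms) are absorbed, since a slow movement can hover
   under threshold at its turnaround for longer than the hold time. When
   a session carries a labeled movement count — part of the experimental
   design — and the defaults miss it, the detector recalibrates over a
   small deterministic grid of threshold and merge-gap values until the
   count is reproduced (with a segment-length uniformity check so a
   fragmented split can never satisfy the count), erring only if no grid
   point matches. At realistic noise levels the duration distributions of
   turnaround dips and noise-shortened rest intervals genuinely overlap,
   so no fixed setting can be correct for every session; pinning the
   detector to the known trial count is how reaching studies resolve
   this in practice.
2. **Time normalization** (`time_normalize()`). Trials of one target are
   linearly resampled to the median trial length before averaging; the
   source of unequal lengths is natural (here: simulated) duration
   variability.
3. **Averaging** (`average_trials()`) over the repetitions of each target.
4. **Filtering** (`lowpass()`): 6th-order Butterworth, 10 Hz cutoff,
   applied forward and backward. The zero-phase choice doubles the
   effective attenuation order and removes phase lag, which matters when
   comparing decoded and recorded trajectories sample by sample; both
   passes start from the steady state of the boundary sample, so constants
   pass through exactly and rest-bounded recordings show no edge
   transients.
5. **Normalization** (`fit_normalization()`): per-channel min/max over the
   training trials mapped to $[-1, +1]$. The record is fitted once on
   training data and applied unchanged to validation and cross-subject
   inputs; out-of-range validation samples map outside $[-1,1]$ without
   clipping and can be counted with `normalization_coverage()`. Shoulder
   velocities (central differences of the filtered angles,
   `angular_velocities()`) get their own record.

The averaged, filtered, normalized movements are concatenated in target
order into the source matrix (`assemble_source_matrix()`), 5 rows by
(targets × samples) columns, which feeds the decomposition.

Decoder training uses all individual segmented trials rather than the 8
averaged movements (15× the sample count); `fit_decoder(averaged_only =
TRUE)` restores the averaged alternative. Per-trial activation targets come
from projecting each trial through the subject's stored decomposition
(`project()`).

## Synergy extraction choices

PCA is computed on the row-centered source matrix via thin SVD
(`extract_synergies()`); the channel means are stored and restored at
reconstruction. The data are already normalized to $[-1,1]$, so no further
scaling is applied before the decomposition. Component signs are fixed so
each loading's largest-magnitude entry is positive, making results
reproducible across linear-algebra backends. The retained count is the
smallest $N$ whose cumulative explained-variance fraction strictly exceeds
the threshold (default 0.85).

## The recurrent decoder

The network is a stack of 1–3 LSTM layers (`n_hidden_layers`) with a linear
output head, consuming windows of the 10 previous time steps of the chosen
input combination (2, 3, 4 or 6 shoulder signals, `select_inputs()`) and
predicting the target at the window's final step. Windows never cross a
movement boundary, so the first 9 samples of every movement produce no
prediction and evaluation drops them accordingly. Training minimizes mean
squared error with Adam; 10% dropout is applied between layers (not to the
recurrent connections). The implementation (forward pass, backpropagation
through time, Adam) lives in compiled code under `src/` and is exercised
against finite-difference gradients in the test suite. All randomness —
initialization, shuffling, dropout masks — flows through one seeded
generator, so training is bit-reproducible for a fixed seed on a given
platform.

Hyperparameters the source protocol leaves open are set to: 64 hidden units
per layer, batch size 32, learning rate 0.005, up to 100 epochs with early
stopping (patience 10) on a 10% held-out fraction of the training windows.
Examples and tests use smaller networks (8–32 units) and 2–30 epochs, which
this task's low dimensionality comfortably supports.

## Evaluation and statistics

`rmse()` pools multiple outputs as the square root of the average
per-output mean squared error, in degrees; `pearson()` and `interpret_r()`
report per-output correlations with the conventional strength bands
(boundary values are assigned to the band of larger $|r|$, so $r = 0.7$ is
"strong" and $r = 0.1$ "weak" — the published band notation overlaps at the
boundaries, and this reading resolves it deterministically).

`anova_from_summaries()` reconstructs the full one-way ANOVA table from
group counts, means and sample variances, so the analysis can be run
either from raw RMSE groups or directly from printed descriptive-statistics
tables (`reported_rmse_summaries()` ships the published ones). Applied to
summaries of raw data it is identical to the raw-data ANOVA.
`tukey_hsd()` computes pairwise studentized-range statistics
$Q = |m_i - m_j| / \sqrt{MS_W / n}$ for equal group sizes, with p-values
and critical values from R's `ptukey()`/`qtukey()`; the Tukey–Kramer
unequal-$n$ variant is deliberately out of scope, matching the balanced
published design.

### Cross-subject transfer

`cross_subject_evaluate()` scores every (target subject A, source decoder
B) pair: A's validation inputs are mapped through **A's** normalization
records, decoded by **B's** network, and — for the synergy methodologies —
reconstructed through **A's** synergy matrix and channel means. Self-pairs
are included, so a cohort of $s$ subjects yields $s^2$ values per
methodology ($196 = 14^2$ at the published design), matching the published
counts; a flag excludes the diagonal.

Because PCA's component frame (sign and within-subspace orientation) is
arbitrary, the substituted subject's retained loadings are first aligned to
the decoder subject's by the best orthogonal transform (Procrustes on the
loading columns) — the standard synergy-matching step when comparing
synergies across individuals. The transform is the identity for self-pairs
and reduces to a per-component sign flip when the frames already agree.
Without it, occasional sign-flipped pairs dominate the cross-subject error
variance for reasons that have nothing to do with the decoders.

## The synthetic cohort generator

No human recordings accompany the method, so `generate_cohort()` emulates
the study design: per subject, a training session of 8 targets × 15
repetitions and a validation session of 35 uniformly drawn targets, at
120 Hz, movements of nominally 1.5 s separated by 0.5 s rests. Each
movement is

$$x(t) = \text{baseline} + B\,c(t) + \varepsilon(t),$$

with $B$ the subject's 5 × 2 orthonormal loading basis, $c(t)$ smooth
latent activations and $\varepsilon$ i.i.d. Gaussian noise (default SD 1°,
the order of a fused IMU orientation output). Generator choices worth
recording:

* **Activation shapes.** Latent $n$ follows
  $\sin(\pi s)^2 \cos((n-1)\pi s)$ on normalized time, scaled to a
  target-specific peak amplitude: latent 1 is the raised-cosine transport
  bump, latent 2 the biphasic out-versus-return component seen in reaching
  kinematics. The two shapes are orthogonal in time; a shared bump shape
  for all latents would make the latent signals nearly collinear within
  every trial and the PCA frame unstable across subjects.
* **Amplitudes.** Per-target peak amplitudes are drawn once per cohort
  (magnitude 15–45°, random sign) and shared across subjects — the task
  and target grid are common. Each further latent's amplitude range
  shrinks by 0.4, producing the strongly ordered variance spectrum
  reported for reaching synergies (first component above 75%, first two
  above 90%).
* **Bases.** The cohort's reference basis is a jittered, orthonormalized
  prototype whose first column couples elbow flexion–extension with
  shoulder flexion and whose second couples pronation–supination with
  shoulder abduction. Dominant entries keep the sign convention stable
  across subjects and guarantee the forearm is genuinely driven by the
  latents; an isotropic random basis does neither. Subject bases add
  Gaussian perturbations of scale `inter_subject_basis_sd` (default 0.2)
  and are re-orthonormalized; 0 gives identical subjects.
* **Trial jitter.** Each trial's duration is scaled by a seeded uniform
  factor in $[0.9, 1.1]$ so the time-normalization path is genuinely
  exercised.
* **Baselines.** Drawn per subject within plausible ranges (shoulder
  ±30°, pronation ±40°, elbow 20–60°), so normalization is never
  degenerate.

What the generator does **not** emulate: sensor physics and orientation
filtering, non-synergy residual variance, movement-to-movement variability
of the activation shapes, fatigue or learning effects, and any
nonlinearity in the joint coupling. Passing tests on this generator show
that the pipeline recovers what the synergy model assumes; they cannot
certify performance on human data.

## Numerical choices and degenerate inputs

* Sample indices are 1-based; movement boundaries and source-matrix block
  boundaries are half-open `[start, end)`.
* Constant channels are rejected at normalization (degenerate range);
  constant recordings raise a segmentation error with the speed-trace
  diagnostics; `speed_threshold = 0` returns the whole recording as one
  segment.
* Movements shorter than the window contribute no training windows; if all
  are shorter, an empty-dataset error is raised.
* Non-finite training loss aborts with the history attached.
* `derive_seed()` hashes a master seed with stage labels into
  $[0, 2^{31})$, so every stage of an experiment is independently
  reseedable and reproducible; collision-freedom over the full 14 × 36
  grid is asserted in the tests.

## Worked example sizes

The examples and tests run cohorts scaled down from the study design
(typically 4 targets × 5 repetitions at 60 Hz with 8–16 hidden units):
these sizes keep the full suite fast while still exercising every stage,
and the parameter-recovery checks use the full 8 × 15 × 120 Hz design. The
acceptance script reproduces the published statistical tables from their
printed group summaries exactly as the statistics layer would consume an
imported CSV of group descriptives.

## Known limitations

* The transfer comparison inherits the generator's idealizations; in
  particular the min–max normalization cancels part of the inter-subject
  scale differences for the direct method too, so effect sizes are smaller
  than a real cohort might show.
* Tukey HSD requires balanced groups (the published design is balanced).
* The LSTM is single-threaded by design for determinism; no GPU path.
* One-synergy decoding reconstructs both forearm channels from a single
  activation, so it is structurally limited whenever the two forearm
  angles are not strongly coupled.
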