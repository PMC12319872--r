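---
title: "Methods: from simulated EEG to decoded ongoing thought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from simulated EEG to decoded ongoing thought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`thoughtprobe` implements a complete analysis pipeline for experience-sampling
EEG studies of ongoing thought: a synthetic data generator with known ground
truth, spectral feature extraction, cluster-based statistics, mixed-model
control analyses, and a shallow convolutional decoder. This vignette records
the modelling assumptions and the reasoning behind the numerical choices; the
README shows a worked example.

## The study design being emulated

The generator mimics a lab protocol in which participants perform a long
self-paced task while thought probes interrupt them at unpredictable moments.
Each probe collects 7-point Likert ratings on seven dimensions of ongoing
thought: `off_task`, `freely_moving`, `sticky`, `goal_directed`, `internal`,
`self`, and `other`. Defaults follow that protocol: 7 participants times 7
sessions, roughly 80 minutes of task per session, 35 probes separated by
uniform 90-150 s gaps, two 5-minute resting blocks with a retrospective
report each, and 32 channels sampled at 256 Hz. At rest the task-relatedness
question is not asked, so `off_task` (and the activity field) are `NA`.

### What the generator models

- **Aperiodic background.** Each channel carries 1/f-shaped noise with
  power spectral density `10^offset * f^-exponent`, synthesized by shaping
  white noise in the frequency domain. Offset and exponent are drawn once
  per participant (uniform on configurable ranges), because in real data
  the aperiodic slope is a stable individual trait.
- **Oscillatory sources.** Narrowband oscillators (by default theta at 6 Hz,
  alpha at 10 Hz, beta at 18 Hz) are produced by Gaussian-envelope filtering
  of white noise and projected to the scalp through fixed topographies.
- **Thought-state effects.** Each probe window has a latent 7-vector drawn
  from a correlated Gaussian (the correlation matrix encodes, e.g., that
  off-task and freely-moving thought co-occur and that off-task and
  goal-directed thought oppose each other). During the seconds preceding a
  probe, the amplitude of a dimension's oscillator over its electrode group
  is scaled by `1 + gain * sign * latent`, so band power carries the
  state. Ratings are a noisy, rounded affine map of the same latent, which
  makes labels imperfect proxies of the signal - as in real reports.
- **Rest blocks** use one latent vector held constant for the whole block
  and a single retrospective rating.

### What it deliberately does not model

Eye blinks, muscle and movement artifacts, electrode drift, line-noise
nonstationarity, volume-conduction mixing beyond the fixed topographies, and
any within-session learning or fatigue trends. The pipeline's artifact
surface (filtering, re-referencing) is still exercised, but cleaning
performance cannot be evaluated with this generator.

## Preprocessing

Recordings are band-pass filtered 1-55 Hz with a 4th-order Butterworth
applied forward and backward (zero phase), notch-filtered at 60 and 120 Hz,
cut into non-overlapping 2-s epochs carrying 1 s of context on each side
(reflection-padded at the recording edges), and re-referenced to the common
average. The context samples exist so that any transient at an epoch edge
stays out of the 2-s core used for spectra.

## Spectral features

Power spectra use Welch's method in the following dialect: 1-s Hamming
windows stepped by 0.5 s (three segments per 2-s core), one-sided density
normalization `2 / (fs * sum(w^2))`, evaluated on the integer grid 4-30 Hz
(27 bins). With 1-s segments the DFT bins land exactly on integer
frequencies, so no interpolation is involved.

The aperiodic component is removed per electrode by a robust straight-line
fit in log10-power vs log10-frequency: an ordinary least-squares line is
refit twice after excluding points lying more than one residual standard
deviation *above* the line (one-sided, because oscillatory peaks only add
power). The **periodic** feature matrix is the residual
`log10(power) - fitted line`, a 32 x 27 matrix per epoch. We chose
fit-and-subtract over an explicit peak-plus-background decomposition
because the downstream statistics need only the residual map, and a linear
robust fit is transparent, fast, and has no convergence failures.

Band summaries use six canonical bands tiling 4-30 Hz: low/high theta
(4-5, 6-7), low/high alpha (8-9, 10-13), low/high beta (14-20, 21-30).

## Labeling and exclusions

Ratings 1-3 map to the `lower` end, 5-7 to `upper`, and the midpoint 4 is
discarded. Trials are the 2-s epochs inside the 12-s pre-probe window
(8 or 16 s are supported), each inheriting its probe's dichotomized label.
A session enters the session-level contrast for a dimension only if both
ends are present. For rest, a dimension is excluded cohort-wide if any
participant lacks one of the ends - a single missing cell would otherwise
unbalance the paired contrast.

For the covariate-controlled model, the three dimensions most correlated
with the dimension of interest are found per participant from within-session
Pearson correlations pooled across sessions by Fisher's z. Ranking uses the
**absolute** pooled correlation: a strong negative correlate confounds the
contrast exactly as much as a strong positive one. Zero-variance rating
columns get r = 0 with a warning rather than an error.

## Cluster-based permutation test

Session-level mean periodic matrices for the two ends are compared with a
paired t-map over all 32 x 27 cells. Cells with `|t|` above the two-tailed
`alpha = .05` quantile of the t distribution (n_pairs - 1 df) are grouped
into clusters by adjacency: two cells are neighbors if they are in the same
frequency bin on adjacent electrodes, or on the same electrode in bins 1 Hz
apart (no diagonal links). Electrode adjacency uses a Euclidean distance
threshold of 0.55 on the unit-circle montage, chosen so that every
electrode has at least two neighbors (mean degree about six) - sparser
graphs fragment genuine effects, denser ones merge distinct ones.

The test statistic is the cluster mass (sum of t values). The null
distribution is the maximum absolute cluster mass under random within-pair
sign flips of the difference matrices, and each observed cluster gets the
Monte-Carlo p-value `(r + 1) / (n_perm + 1)`. Sign flipping is the exact
permutation scheme for a paired design under exchangeability of the pair
ordering. The permutation loop is vectorized (one flips-by-differences
matrix product per batch), which keeps 1000 permutations on the full grid
below a second.

## Mixed models

The response is the mean periodic power inside the significant-cluster mask,
one value per session per end. The primary model is
`response ~ end + (1 | participant) + (1 | participant:session)`, fitted by
maximum likelihood so that the end effect can be tested by a likelihood
ratio against the nested model without `end`. The covariate model replaces
the session random effect with the three correlated-dimension mean ratings:
`response ~ end + cov1 + cov2 + cov3 + (1 | participant)`. Singular fits
(a variance component at zero, common at small simulated scales) are
flagged, not raised; collinear covariates trigger a warning. Wald 95%
intervals for the end effect are reported alongside the LRT p.

## Task-rest comparison

Whether the task-state signatures reappear at rest is quantified by the
Pearson correlation between two grand-average **difference** maps
(upper minus lower, averaged over included sessions): one from task trials,
one from rest epochs labeled by the retrospective report. Correlating
difference maps rather than raw maps removes the shared aperiodic and
montage structure that would otherwise inflate the similarity.

## Decoding

The classifier is a deliberately shallow 1-D CNN over the 32 x 27 periodic
matrix (channels as input planes, frequency as the spatial axis): 25 filters
of length 7, ReLU, 20 filters of length 5, ReLU, global average pooling,
dropout 0.1, and a 2-unit softmax - 8187 parameters. It is implemented in
base R with exact backpropagation (gradients verified against finite
differences in the tests) and Adam, early stopping on a held-out validation
split with best-weights restoration. A network this small trains in seconds
on a CPU and cannot memorize much, which matches the modest trial counts of
experience-sampling data.

Features are z-scored with means and SDs estimated on the training split
only. Class imbalance is handled by SMOTE on the training split only:
synthetic minority points are drawn uniformly on segments between a
minority sample and one of its k nearest minority neighbors (k capped at
n_minority - 1). Evaluation reports MCC, balanced accuracy, and AUC.

Two evaluation regimes are provided:

- **Within-participant**: 5-fold cross-validation per participant, with 10%
  of each training fold reserved for validation; participants need at least
  50 trials per class (configurable) to enter.
- **Leave-one-subject-out with transfer**: a base model is trained on all
  other participants, then the held-out participant's data is split into an
  adaptation pool (25%) and a test set (75%); the base model is fine-tuned
  on the SMOTE-balanced adaptation pool and tested on the untouched 75%.
  The unadapted base model is evaluated on the same test set for
  comparison, and an index audit (train/validation/adaptation/test trial
  ids) is returned so leakage checks are mechanical.

Statistical significance of decoding uses label permutation: the pipeline
is run 25 times on true labels and 25 times on labels shuffled *within
participant* (preserving class imbalance), giving a rank-based permutation
p and a one-sided Wilcoxon rank-sum test between the two sets of scores.

## Reproducibility and scaling

All stochastic stages derive their seeds from one root seed through
`stage_seed()`, a stable string hash into `[0, 2^31)`; repeated runs are
bit-identical. Generator defaults match the emulated full-scale protocol;
the test suite and the acceptance script run scaled-down cohorts (shorter
probe gaps, fewer probes and sessions, fewer training epochs, a lower
trial threshold) purely so the whole battery fits in a CI budget - effect
sizes and every algorithmic constant stay at their defaults.

## Command-line workbench

`cli_run(command, config, out_dir)` (with the thin wrapper in
`inst/cli/thoughtprobe.R`) stages the pipeline on disk: `simulate` writes
EDF recordings, report tables, and ground-truth JSON; `features`, `label`,
`cluster-test`, `lmm`, `similarity`, `classify`, and `report` each read the
previous stage's artifacts and add their own, tracked in a manifest.
Recordings are stored as standard 16-bit EDF (the codec is part of the
package and round-trips within one quantization step); tabular artifacts
are CSV and statistical summaries JSON, so every intermediate is inspectable
with ordinary tools.

## Limitations

The generator's ground truth makes recovery testable but also idealized:
effects are stationary, topographies fixed, and reports are conditionally
independent given the latent state. Decoding accuracies on synthetic
cohorts should be read as pipeline checks, not as forecasts of performance
on human data. The EDF codec covers the subset of the format the pipeline
emits (one-second records, identical sampling rates across channels), not
arbitrary files from other systems.
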