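---
title: "Classifying interictal resting-state MEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying interictal resting-state MEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(megelm)
```

## The problem

Interictal brain activity — recorded between seizures and cleaned of any
epileptiform discharge — still carries information about whether a brain is
epileptic, and about the epilepsy type. `megelm` implements a pipeline that
classifies subjects as healthy, generalized-epileptic or focal-epileptic from
multichannel resting-state MEG segments, using only two families of
per-segment features:

* **spectral power**: total and relative power spectral density (PSD) per
  sensor on 18 fine bands of 2 Hz spanning 4–40 Hz;
* **phase synchronization**: the phase-locking value (PLV) and the phase-lag
  index (PLI) between all sensor pairs on the same bands, reduced to a
  per-sensor connectivity strength.

A randomized-mapping classifier (an extreme learning machine, ELM) is
trained on segment-level feature vectors; subject decisions follow from a
majority vote over the subject's segments, under subject-wise leave-one-out
cross-validation; and a two-stage cascade of binary classifiers assigns the
three-way diagnosis.

Since the clinical recordings behind the original analysis are not public,
the package ships a synthetic-cohort generator whose classes differ in
exactly the statistical signals the features are designed to detect. All
quantitative statements about pipeline behaviour in this vignette are
properties of that generator, computed by the package's own tests and
scripts — they are not reproductions of clinical results.

## Pipeline and model

### Segment selection

Given a long multichannel recording, `select_stationary_segments()` tiles it
into non-overlapping contiguous windows, scores each window by the mean KPSS
level-stationarity statistic across sensors, and keeps the `n_select` lowest
scores (the most stationary windows). The KPSS statistic is
\[
  \eta = \frac{T^{-2}\sum_t S_t^2}{\hat{\sigma}^2_{LR}},\qquad
  S_t = \sum_{s\le t}(x_s - \bar{x}),
\]
with a Newey–West long-run variance (Bartlett weights, truncation lag
$\lfloor 4 (T/100)^{1/4}\rfloor$). Choices the data do not dictate:

* windows are non-overlapping (maximizes independence between segments);
* multichannel aggregation is the mean across sensors (`aggregate` argument
  makes this configurable);
* ties are broken toward the earlier start time, for determinism.

The synthetic generator emits segments directly, so this stage is bypassed
in the synthetic workflow; it exists for recording-level input.

### Spectral features

`total_psd()` uses a Welch estimate: Hann-tapered windows, 50% overlap,
per-window mean removal, one-sided density scaling; the band value is the
integral of the estimate over the half-open band $[f, f+2)$. The default
window is half the segment duration capped at 2 s. At this resolution
(0.5 Hz on 5-s segments) the tapered mainlobe of a mid-band tone stays
inside its 2-Hz band and a flat spectrum distributes band shares exactly
proportionally to bandwidth; with 1-s windows (1 Hz bins) half of the
mainlobe of a tone at a band centre would leak into the neighbouring band.

`relative_psd()` divides each sensor's band powers by that sensor's summed
power over the grid, so rows sum to one. The denominator is restricted to
4–40 Hz rather than the full recorded bandwidth: this makes the feature
self-contained (independent of how much out-of-band power the acquisition
chain passes) and is the convention all package defaults use; total PSD
remains available as its own feature kind.

### Phase-synchronization features

For each fine band, `band_phases()` isolates the band with an FFT-domain
mask (raised-cosine transitions of 0.5 Hz) and builds the analytic signal in
the same transform; the instantaneous phase is its argument. The first and
last 10% of samples are discarded before any phase statistic, as a guard
against the wrap-around transients of circular convolution. An FFT mask was
chosen over a forward–backward IIR filter because 2-Hz passbands at kHz
rates put IIR poles too close to the unit circle for stable filtering at any
reasonable order, while the mask is exactly zero-phase at any bandwidth. A
band must span at least two FFT bins, or the call errors out
("band too narrow").

For two phase series, `plv_pair()` is
$\mathrm{PLV} = |\langle e^{i(\phi_1 - \phi_2)}\rangle|$ and `pli_pair()` is
$\mathrm{PLI} = |\langle \mathrm{sign}\sin(\phi_1 - \phi_2)\rangle|$. PLV is
1 exactly when the phase difference is constant (zero-lag coupling
included); PLI is blind to zero-lag coupling and measures the asymmetry of
the phase-difference distribution. For independent phases over $T$ samples
the expected PLV is approximately $\sqrt{\pi}/(2\sqrt{T})$; after narrowband
filtering the effective $T$ is roughly segment-seconds × bandwidth, so
chance PLV levels on short segments are far from zero — a reason the
features use many segments per subject.

`connectivity_matrix()` computes all unordered pairs; `threshold_proportional()`
keeps the fixed proportion of largest links (40% for PLV, 50% for PLI — the
"most significant values" are read as the largest values at a fixed
proportion, not a surrogate-based significance test), ties at the cutoff
resolved by pair index; `sensor_strength()` averages each row over all
$n-1$ partners, zeroed links included in the denominator, matching an
average "over all $j \ne i$". Thresholding is applied per segment and per
band. Both conventions (denominator, per-segment thresholding) are the
simplest readings of the procedure and are kept fixed throughout.

### The classifier

One ELM member maps a $d$-dimensional input through a fixed random matrix
$W_{in} \sim U[-1,1]^{d\times D}$:
\[
  r(n) = F(\eta\, z(n)), \qquad z(n) = \mathrm{standardize}(W_{in}^\top x(n)),
  \qquad F(z) = \sin^2(z + \phi),
\]
and only the readout $o(n) = W_{out}^\top [1; r(n)]$ is trained, by ordinary
least squares on ±1 targets (SVD-based minimum-norm pseudoinverse;
an optional ridge penalty exists but defaults to off, matching the
"simple linear regression" design). Standardization statistics (per hidden
unit) are estimated on the training pass and frozen for prediction, so no
test-set information leaks into the representation. The wording "first
multiplied by $W_{in}$ and then normalized" is implemented literally:
standardization acts on the mapped pre-activations, not on the raw inputs.

Because a single random $W_{in}$ realization is noisy, `fit_ensemble()`
trains `n_ensemble` members with independent $W_{in}$ (seeds derived from a
master seed by a counter scheme) and `predict_ensemble()` takes a majority
vote; the positive-vote fraction doubles as the ROC score. $\sin^2$ is
$\pi$-periodic in $\phi$, so $\phi$ and $\phi + \pi$ give identical
classifiers — a property the tests assert exactly.

Parameters and defaults:

| parameter | reference value | desk-scale value | meaning |
|---|---|---|---|
| `D` | 350 | 100 | hidden units; must stay well below the example count |
| `eta` | 0.1 | 0.1 | input scaling, sets the activation's operating range |
| `phi` | 2.1 | 2.1 | activation phase, sets the degree of nonlinearity |
| `n_ensemble` | 100 | 11 (5 in scans) | members in the majority vote |

Ties: an ensemble vote of exactly 1/2 and a subject segment-vote of exactly
1/2 both resolve to the positive (pathological) class. This maximizes
sensitivity, which is the clinically conservative direction; both rules are
deterministic and documented at the function level.

### Cross-validation, cascade, metrics

`make_folds()` builds $k$ folds from $k$ subjects per condition: fold $i$
tests the $i$-th subject of every condition after a seeded within-condition
shuffle, so every subject is tested exactly once and train/test subjects
never overlap — the subject-wise design that prevents within-subject
leakage. Unbalanced designs are rejected rather than silently stratified.

`run_stage()` fits a fresh ensemble per fold and pools one subject-level
confusion matrix over folds (per-fold accuracies are also returned); the
segment-level ROC pools the held-out vote fractions, each segment being
held out exactly once. `run_cascade()` shares the fold partition between
the two stages: stage 2 is trained only on the pathological training
subjects of the same fold, and a control subject mis-labelled pathological
at stage 1 is scored by the stage-2 model of its own fold — its segments
never occur in any training set that predicts them.

`confusion_metrics()` implements accuracy $(TP+TN)/N$, sensitivity
$TP/(TP+FN)$ and specificity $TN/(TN+FP)$; for the three-class cascade,
accuracy is trace/total and specificity is the control-class recall, with
per-class recalls also reported. `roc_auc()` sweeps the unique scores and
integrates by trapezoid; it equals the Mann–Whitney pairwise probability
with ties counted 1/2, which the tests verify against a brute-force count.

## The synthetic generator

`generate_cohort()` emulates a three-condition cohort (14 subjects per
condition, 40 × 5-s segments at 1 kHz over 102 sensors at full scale). Each
sensor is Gaussian $1/f^{\alpha}$ noise synthesized in the frequency domain
($\alpha = 1$ by default, a generic resting-MEG-like background), and each
class is characterized by:

* **band-power boosts** — multiplicative spectral power factors on canonical
  bands, with a per-subject lognormal multiplier (sd 0.1 on the log scale)
  creating between-subject variability while keeping power positive;
* **phase coupling** — within a coupled band, sensor $k$ receives
  $\sqrt{s}\,Z\,e^{-i(k-1)\lambda} + \sqrt{1-s}\,N_k$, a mixture of a shared
  narrowband Gaussian source $Z$ (rotated by the per-sensor lag $\lambda$)
  and independent narrowband noise $N_k$.

The mixing model was chosen over static von-Mises phase offsets because a
static offset gives a constant phase difference within a segment — PLV = 1
at every concentration — and therefore cannot encode graded coupling. The
mixture has the exact limits the pipeline needs (independence at $s=0$,
constant lagged phase difference and hence PLV = 1 at $s=1$) and mean PLV
monotone in $s$, which the property tests check.

The planted class contrasts are fixed generator choices (the source cohort
is not public and reports no effect sizes): generalized = beta-1 power ×2.0
and beta-2 coupling 0.35; focal = beta-1 power ×1.3 and beta-2 coupling
0.10; healthy = baseline with beta-2 coupling 0.10. They were calibrated
once so that a desk-scale cohort resolves both contrasts without saturating
the band-pair grid (balanced-stage AUC around 0.93–0.98), and are not tuned
per experiment.

What the generator does **not** emulate: sensor geometry and field spread
(every sensor is statistically exchangeable), artifacts (blinks, cardiac,
muscle), non-Gaussian or nonstationary dynamics, epileptiform discharges,
and any spatial structure of the epileptic focus. Passing tests therefore
demonstrate that the pipeline recovers band-power and phase-coupling
contrasts of the planted kind — not that it would reach any particular
accuracy on clinical MEG.

## Problem sizes and determinism

The desk-scale profile used by the analysis scripts, tests and the
acceptance script is 12 sensors at 160 Hz, 2-s segments, 10 segments per
subject, 14 subjects per condition, with `D = 100` and 11 ensemble members
(5 during 25-cell band-grid scans, where the spec of the experiment allows
reduced ensembles). These sizes keep a full cross-validated experiment in
the tens of seconds while leaving every statistical contrast detectable;
the full-scale geometry remains available through `cohort_config()` and
`elm_params()`.

A single master seed fans out through `derive_seed(master, what)` to the
generator, the fold shuffle and the ensemble members, so
`run_experiment()` is end-to-end deterministic and every reported number is
traceable to a logged configuration (`metrics.json` stores all derived
seeds).

## Null calibration

With three identical class specifications the pipeline must not find
structure. Two checks cover this: the segment-level AUC of the
healthy-vs-epileptic stage sits at 0.5 within Monte-Carlo error, and the
pooled subject accuracy of the **balanced** generalized-vs-focal stage over
ten master seeds lies within the 95% binomial interval around 0.5. The
balanced stage is the right chance-0.5 comparison: the healthy-vs-epileptic
contrast is 14 vs 28 subjects, and under a null cohort a least-squares
readout learns that prior, pushing subject accuracy toward the majority
rate 2/3 rather than 0.5.

## Known limitations

* PLI on short desk-scale segments is noisy (few effective independent
  phase samples per 2-Hz band), mirroring its reported unreliability at the
  sensor level; the default feature set for the synthetic experiments is
  relPSD + PLV.
* The cohort store is a plain-text directory (CSV segments + CSV manifest +
  JSON metadata); it round-trips exactly but is not a binary scientific
  container, and very large cohorts should be regenerated from seed rather
  than stored.
* `kpss_statistic()` implements the level-stationarity variant only; trend
  stationarity is out of scope for segment ranking.
* Vendor MEG formats are not read; recording-level input is the documented
  plain-text layout.
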