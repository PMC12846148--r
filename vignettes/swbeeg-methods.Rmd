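---
title: "Methods: linking short-term subjective well-being to EEG band features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking short-term subjective well-being to EEG band features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swbeeg)
```

## The problem

Office-comfort studies increasingly ask whether momentary subjective
well-being (SWB) — a verbal comfort rating on a 1..10 scale, reported every
~30 s while ambient temperature and humidity vary — leaves a readable trace
in the EEG. `swbeeg` implements a complete analysis chain for this question
on 14-channel recordings (10-20 montage AF3, F7, F3, FC5, T7, P7, O1, O2,
P8, T8, FC6, F4, F8, AF4; 128 Hz):

1. **Features.** For every report, the closed 10 s pre-report window
   (1281 samples at 128 Hz) is reduced to the relative power of the five
   conventional bands (delta 0.5-3, theta 4-7, alpha 8-13, beta 14-30,
   gamma 31-55 Hz) at each channel, and to the frontal alpha asymmetry
   (FAA), `ln pow_alpha(AF4) - ln pow_alpha(AF3)`.
2. **Classification.** A leave-one-out 1-nearest-neighbour classifier
   predicts the SWB rating from single features, one band across all 14
   channels, all 70 features, or band-filtered raw series (Euclidean or
   DTW distance), scored by MSE — squared error respects the ordinal scale.
   Winner tallies across participants are tested against chance with a
   chi-squared goodness-of-fit, standardized residuals, and an exact
   binomial test.
3. **Regression.** Per participant and feature, SWB is regressed on the
   feature after SMOTE balancing (ratings are heavily mid-concentrated);
   the slope is averaged over ten SMOTE seeds, then a two-sided one-sample
   t-test across participants with Cohen's d, 95% CI and Benjamini-Hochberg
   FDR over the full 5 x 14 family.
4. **Transfer distance.** Participant A's fitted predictor applied to
   participant B's data yields `dist(A,B) = mean |SWB_true - SWB_pred| /
   #unique(SWB_true)`; dividing by the number of distinct ratings makes the
   error comparable across participants with different rating ranges. The
   asymmetric matrix is symmetrized by the pairwise minimum.
5. **Clustering consistency.** The symmetrized matrix is embedded by Isomap
   (neighbourhood 1, precomputed distances), partitioned by k-means for
   k = 2..6, scored by the mean silhouette `s = (b - a) / max(a, b)`, and
   partitions from different feature families are compared with the
   adjusted Rand index.

Because raw recordings of this kind are rarely shareable, the package ships
a synthetic cohort generator with known ground truth so that every stage is
testable end to end.

## The synthetic cohort

Each participant carries a latent comfort level \(z(t)\), a stationary
Ornstein-Uhlenbeck process sampled on the report grid (AR(1) with
autoregression \(e^{-\Delta t/\tau}\), standard-normal marginals). Comfort
drifts slowly relative to the 10 s feature window, so the default time
constant is \(\tau = 60\) s.

Ratings are a monotone squashing of the latent level:
\(u = \tanh(b\,z)/b\) (identity at \(b = 0\)), then
\(\mathrm{SWB} = \mathrm{round}_{1/2\uparrow}(5.5 + 1.5\,u)\) clipped to
1..10. The compression parameter \(b\) (default 1) reproduces the mid-heavy
rating histograms seen in practice; \(z = 0\) always maps to 6.

EEG is a sum of independent band-limited unit-variance Gaussian noises whose
amplitudes are modulated by the latent level:

\[
x_c(t) = \sum_b A_b \,\bigl(1 + \beta_{bc}\, z(t)\bigr)\, n_{bc}(t)
         + \sigma\, \varepsilon_c(t),
\]

with baseline amplitudes \(A\) following the usual 1/f-like decline (delta
20, theta 10, alpha 15, beta 5, gamma 3 uV; broadband noise 2 uV) and
coupling slopes \(|\beta| < 1\) so amplitudes stay positive. Band noise is
generated spectrally — complex Gaussian coefficients on the in-band bins,
Hermitian-symmetric — which is exactly band-passed Gaussian noise with a
brick-wall filter and keeps the five band components independent by
construction. The latent level is held piecewise-constant between reports.
Cohorts plant coupling clusters: all members of a cluster share its
\(\beta\) up to additive jitter (SD 10% of the cluster slope), with
independent latent paths and noise.

What this generator does **not** emulate: eye-blink/EMG artifacts, volume
conduction and channel correlation, 1/f background within bands,
non-stationary noise floors, or rating noise uncorrelated with the latent
state. Passing recovery tests therefore show that the pipeline's inference
is correct when its own assumptions hold — not that real EEG satisfies
those assumptions.

## Numerical and design choices

* **Power estimator.** Welch PSD with 2 s Hann segments and 50% overlap,
  integrated over the band by the trapezoidal rule. The estimator for the
  published analysis is unstated; Welch is the community default and
  stabilises 10 s windows (nine segments). Bands reaching above Nyquist are
  truncated at `fs/2` (the gamma band is defined to 55 Hz, recording
  devices of this class roll off near 43 Hz; truncation is the neutral
  resolution).
* **Relative-power denominator.** The sum of the five band powers, not the
  broadband total, so channel columns sum to exactly 1 and the feature is
  independent of device bandwidth.
* **Filters.** Analysis band-passes are 4th-order Butterworth applied
  forward-backward (zero phase, length-preserving).
* **Window convention.** The epoch is the closed interval of
  `round(10 * fs) + 1` samples ending at the report-time sample — 1281
  samples at 128 Hz. Reports arriving before one full window are skipped
  with a warning rather than failing the recording.
* **1-NN.** k = 1 because the rating distribution is imbalanced and larger
  k can never predict rare ratings; no feature standardisation (relative
  powers already live in [0,1]); distance ties break to the lowest instance
  index, making evaluation order-stable. Ratings reported only once are
  removed before leave-one-out evaluation, and a participant is evaluable
  only if at least two distinct ratings remain.
* **DTW.** Squared-cost convention: local cost is the squared Euclidean
  distance across channels, the distance is the square root of the minimal
  cumulative cost (the convention of the common time-series toolkits).
  This makes DTW of equal-length series never exceed their Euclidean
  distance, since the identity path is admissible. Euclidean is the default
  metric for series (DTW is retained behind a flag; it is far slower and
  was not better in the motivating analyses).
* **SMOTE.** Convex interpolation between same-class nearest neighbours,
  k = 5 shrunk to class size minus one; every class is raised to the
  majority count. Classes with a single member are removed first. Slopes
  (and intercepts) are averaged over seeds 1..10.
* **FDR family.** m = 70 (5 bands x 14 channels), with unlisted tests
  treated as p = 1 when only a subset of p-values is supplied; this leaves
  the adjustment of the supplied ones unchanged.
* **Transfer predictions.** Linear models predict real values clipped to
  [1, 10] without rounding — the transfer distance uses absolute error, and
  rounding would discard information. Self-distance is defined as 0. The
  usability filter (at least `min_epochs` epochs, default 20, and at least
  two distinct ratings after singleton removal) mirrors the exclusion of
  constant reporters and too-short recordings.
* **Isomap.** Symmetric 1-NN graph on the precomputed distances; a
  disconnected graph is repaired by adding minimum-weight bridging edges
  between components (keeping the stated neighbourhood size everywhere
  else, and logged in the result); geodesics by shortest paths; classical
  MDS via `cmdscale`.
* **k-means.** `stats::kmeans` (Hartigan-Wong) with 50 random restarts
  under a fixed seed, best fit by within-cluster sum of squares. With at
  most a few dozen points the best-of-restarts solution is insensitive to
  the init scheme, so no k-means++ init is needed. k = n is special-cased
  to singleton clusters (zero scatter). Labels are renumbered in order of
  first appearance so reruns are comparable.
* **Silhouette.** Computed on Euclidean distances in the embedding space
  (the partition is found there; scoring in the same space is the
  consistent choice), with `is_dist = TRUE` available to score on the
  symmetrized distances instead. Singleton clusters score 0.
* **Handedness** is stored on recordings and used in exactly one place: the
  group regression tests exclude left-handed participants by default
  (`include_left_handed = FALSE`), because their slopes tend to run opposite
  to the right-handed majority and there are too few of them for a separate
  group test. No other computation branches on it.

## Validation studies and their sizes

The test suite ties every stage to an independent oracle (brute-force 1-NN
scan, exhaustive DTW path enumeration, explicit-loop silhouette, normal
equations, contingency-table ARI cross-checked against `mclust`) and runs
three recovery studies against the generator's ground truth:

* **Null calibration** — 200 uncoupled cohorts of 5 participants x 20
  reports: the fraction of the 70 x 200 group tests with uncorrected
  p < 0.05 must lie within 0.05 +/- 0.03.
* **Sign recovery** — 100 single-participant cohorts with gamma coupling
  +0.5 and 60 reports: the seed-averaged regression slope of relative gamma
  power must be positive in at least 95 runs.
* **Cluster recovery** — 50 two-cluster cohorts (3 participants per
  cluster, gamma coupling +/-0.5, 40 reports) pushed through the full
  feature -> transfer-distance -> Isomap -> k-means chain: adjusted Rand
  >= 0.8 against the planted labels in at least 80% of runs.

These studies use compressed sessions (one report every 10.5 s instead of
30 s): the properties under test — test calibration, slope sign, cluster
geometry — depend on the number of reports and the coupling, not on the
wall-clock spacing of reports, and the shorter sessions keep the simulated
sample counts proportionate. The sign-recovery and cluster studies keep the
strong-coupling regime (\(|\beta| = 0.5\)) and 40-60 reports per
participant, commensurate with the ~70 usable reports of a real session
set.

## Known limitations

* The generator's coupling is linear in the latent level and shared across
  channels within a band; planted clusters are therefore easier to recover
  than any subgroup structure plausible in real cohorts.
* Transfer distances are not metrics (no triangle inequality), and with
  neighbourhood size 1 the Isomap graph is almost always repaired; both are
  properties of the published design, reproduced deliberately.
* The FAA transfer model regresses SWB on FAA so that predictions are in
  rating units; the reverse orientation is equally defensible given the
  source material.
* With ~30 participants, partitions into more than 6 clusters would leave
  near-singleton clusters, so candidate k stops at 6.
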