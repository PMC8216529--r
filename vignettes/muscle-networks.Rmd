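---
title: "Methods: synthetic EMG cohorts, intermuscular coherence, muscle networks and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic EMG cohorts, intermuscular coherence, muscle networks and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and design decisions behind
`musclenet`, in the order the pipeline runs them.  It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## 1. The synthetic EMG cohort generator

### Signal model

Each of the six channels (SCM, SC, UT, left and right) of a recording is

$$x_c(t) \;=\; A_c\, e_c(t) \Big[ \sum_b \kappa_{c,b}\, u_b(t) +
\eta_{c,b}\, \nu_{c,b}(t) \Big] \;+\; \varepsilon\, w_c(t),$$

where $u_b$ is a zero-mean, unit-variance Gaussian process band-limited to
band $b$ and *shared* by the channels of that drive, $\nu_{c,b}$ are
independent band-limited noises, $w_c$ is broadband measurement noise,
$e_c$ a periodic gait envelope and $A_c$ an amplitude scale.  With
$\kappa^2 = \gamma$ and $\eta^2 = 1 - \gamma$, channel $c$ carries
shared-power fraction $\gamma_{c,b}$ in band $b$, and the standard result
for $x = a s + n_1$, $y = b s + n_2$ with independent noises gives the
population band coherence

$$\mathrm{MSC}_{cd}(b) = \gamma_{c,b}\,\gamma_{d,b},$$

which `expected_msc()` returns as the analytic oracle.

**Band-limiting.** Drives and band noises are produced by zero-phase FFT
masking of white noise (all Fourier coefficients outside the band set to
zero, inverse transform, standardized).  We chose the FFT mask over an IIR
band-pass because a fourth-order Butterworth at 1–4 Hz with a 1000 Hz
sampling rate is numerically unstable in transfer-function form, and
because the mask makes the in-band spectrum *exactly* flat — the property
that keeps the closed form above exact rather than "exact up to filter
rolloff".

**Gait envelope.** $e_c(t) = 0.2 + 0.8\,(0.5(1+\sin(2\pi f_s t +
\phi_c)))^2$ with stride frequency $f_s$ (default 1 Hz) and per-channel
phase $\phi_c = 2\pi(c-1)/6$: nonnegative, periodic, never fully silent.
The exact shape is a modelling convenience; nothing downstream depends on
it.

An important estimator interaction: the closed form
$\gamma_c\gamma_d$ is exact for a *flat* envelope.  Under the gait
envelope, segment-level amplitude modulation (different phases on the two
channels) attenuates the segment-averaged coherence estimate below the
analytic value — measured at roughly 0.19 instead of 0.25 for
$\gamma = 0.5$ on both channels.  The generator therefore exposes
`envelope = c("gait", "flat")`; parameter-recovery tests and the
acceptance checks run in the flat-envelope regime where the oracle is
valid, while the cohort-level pipeline tests use the realistic gait
envelope, for which only directional and monotonicity claims are asserted.

### Default study conditions

The defaults of `cohort_params()` are fixed once and mirror the study
protocol: 20 subjects per group, two tasks (rectilinear, curvilinear; the
"combine" view pools them and is never generated as a third task), three
trials per task, 1000 Hz sampling.  Trial duration defaults to 10 s — the
walking bouts of such protocols last several seconds, and 10 s yields 60
non-overlapping 0.5-s coherence segments per subject and task, enough to
push the MSC estimator bias (≈ 1/segments) below 0.02.  Two drives are
configured:

* a **delta** (1–4 Hz) common drive across all six muscles with
  $\gamma = 0.6$ — the low-frequency common synaptic input associated with
  force production during gait;
* a **beta** (12–25 Hz) drive with $\gamma = 0.3$ — weaker corticospinal
  coupling, giving a second, unaffected band.

The group effect enters only through $\gamma$ and the amplitude scale: in
the CNP group *during curvilinear gait only*, the delta-band $\gamma$
drops by 0.25 (to 0.35) and SCM amplitude rises by 30%.  The source study
reports no effect sizes, so these magnitudes are explicit, configurable
defaults chosen for testability, not claims about any patient population.
Broadband noise power defaults to 5% of the band-limited signal power.

Every recording draws from its own stream, seeded by a pure function of
(master seed, subject number, task, trial), so regeneration is
bit-identical and independent of generation order.

### What the generator does not emulate

No gait kinematics, no motor-unit physiology, no 16-bit quantization, no
nonstationarity beyond the periodic envelope, no artifacts (motion, ECG).
Consequently, passing tests demonstrate that the *estimators and the
pipeline plumbing* behave correctly under known ground truth — not that
the classification accuracies would transfer to real recordings.

## 2. Preprocessing

The conditioning chain is a zero-lag fourth-order Butterworth band-pass
(10–500 Hz) followed by a zero-lag second-order IIR notch at 50 Hz, then
amplitude normalization, then windowing.  Three decisions deserve note:

* **Nyquist clip.** A 500 Hz band edge equals the Nyquist frequency at
  1000 Hz and is not realizable; the filter clips it to 495 Hz and warns.
* **Normalization.** "Maximal EMG amplitude over an epoch of 0.5 s per
  muscle per task" is interpreted as the maximum 0.5-s epoch *RMS* across
  all trials of the task — robust to single-sample artifacts.  The
  single-sample epoch-peak variant is available via
  `norm_method = "peak"`.  Normalization follows filtering and precedes
  windowing.  Note that this per-channel, per-task normalization removes
  pure between-group amplitude *scale* differences from the feature table
  by construction; a group amplitude effect survives only through its
  interaction with the fixed broadband noise floor (a signal-to-noise,
  i.e. spectral-shape, effect).
* **The wideband path.** A 10 Hz high-pass is incompatible with 1–4 Hz
  coherence analysis: measured on the generator, the forward–backward
  high-pass reduces delta-band MSC to a γ-independent ≈ 0.03, because the
  delta residual is attenuated by ~110 dB and the delta bins become
  dominated by spectral leakage from the pass-band.  Since MSC is
  invariant to any filter gain applied equally to both channels, the
  band-pass contributes nothing to coherence in the first place.  The
  preprocessed cohort therefore carries two signal sets: the fully
  conditioned signals (for amplitude and spectral features, faithful to
  the printed chain) and a notch-only "wideband" set consumed by the
  coherence and network modules.

The notch bandwidth defaults to 2 Hz (quality factor 25); none is printed
in the source description.

## 3. Feature extraction

Ten features per channel per non-overlapping 500-ms window, averaged over
all windows of all trials of a (subject, task): MAV, RMS, VAR, WL, SSI in
the time domain; MNF, MDF, PKF, MNP, TTP from the one-sided FFT
periodogram (DC excluded, Parseval-normalized).  Aggregation across
windows is the arithmetic mean — the window-to-subject step is not
specified in the source description, and subject-level samples (40 rows
per task) match the confusion-matrix arithmetic of the published
curvilinear rows.

Two definitional quirks are implemented as printed and documented rather
than silently corrected:

* **VAR** is $\sum x_i^2/(N-1)$ with *no mean subtraction* — band-passed
  EMG is near zero-mean, and the conventional table in this literature
  prints exactly this form.  Hence the identities
  $SSI = (N-1)\,VAR = N\,RMS^2$ hold exactly and are tested.
* **PKF** is printed as $\max P_j$ (a power); the name says *peak
  frequency*.  The default returns the frequency of the maximal bin (ties
  toward the lowest frequency); `pkf = "power"` gives the literal printed
  variant.

MSC features are band means over the three within-side muscle pairs
(SCM–SC, SCM–UT, SC–UT) per side — 5 bands × 3 pairs × 2 sides = 30
columns — plus a broadband 1–30 Hz mean per pair (6 columns), since the
published selected-feature table lists a single undifferentiated "MSC"
feature without naming a band; no guess about that band is hard-coded.

## 4. Coherence estimation

`msc()` is a Welch-type estimator: auto- and cross-spectra averaged over
0.5-s rectangular segments (matching the non-overlapping analysis
windows), $\mathrm{MSC} = |\bar P_{xy}|^2 / (\bar P_{xx}\bar P_{yy})$.
With a single segment the estimator is identically 1, so at least two
segments are required.  For independent signals the expected estimate is
≈ 1/L with L segments; tests assert this bias law and its decrease in L.
Segments never span a trial join, to avoid discontinuity inflation.
Overlap defaults to 0% and is configurable.

Band aggregation assigns bins by lo < f ≤ hi, so shared band edges are
counted once.  At the default 0.5-s segments the frequency resolution is
2 Hz, leaving the delta band exactly two bins (2 and 4 Hz); how the source
study resolved delta-band coherence at that window length is unknown.  The
default keeps 0.5 s for fidelity; a longer coherence segment is a
one-line config change (`coherence_config(seg_s = 2)`), not a silent
substitution.

## 5. Functional muscle networks

Edge weights are band MSC over all 15 channel pairs.  Cross-side pairs are
included by default even though the MSC *classification features* use
within-side pairs only: the published network figures display cross-side
connections, and a within-side-only graph is two disconnected triangles
with degenerate betweenness.  `pairs = "within_side"` restores the
restricted variant.

**Proportional threshold.** The ⌈p·15⌉ largest upper-triangle weights are
retained (ties broken by fixed lexicographic pair order), the rest zeroed;
retained edges keep their weights.  Every subject therefore has identical
connection density regardless of weight scale.  The source density is not
published; the default p = 0.5 is exposed prominently in the run config.

**Metrics.** Strength is the row sum.  Betweenness uses edge lengths 1/w —
the conventional mapping for connectivity weights — with fractional
counting of equal-length shortest-path ties (via igraph), normalized by
(n−1)(n−2)/2.  Both metrics are verified against exhaustive brute-force
oracles on random 6-node graphs to 1e−9.  Because the published per-node
strength values (≈ 0.9) are on the scale of a mean edge weight rather than
a sum over five incident edges, `strength_mean` (strength/degree) is also
reported in the group comparisons.

Group analysis averages the metric across the six nodes per subject and
compares groups with the pooled-variance t-test; group-mean adjacencies
are exported as edge lists for external plotting.

## 6. NCA feature weighting

`nca_fit()` maximizes the expected leave-one-out stochastic
nearest-neighbour accuracy

$$F(w) = \sum_i \sum_{j \ne i,\, y_j = y_i} p_{ij} \;-\; \lambda \sum_r w_r^2,
\qquad
p_{ij} = \frac{\exp(-d_w(x_i, x_j)/\sigma)}{\sum_{l \ne i} \exp(-d_w(x_i, x_l)/\sigma)},$$

with the feature-weighting distance $d_w(x_i,x_j) = \sum_r w_r^2
|x_{ir} - x_{jr}|$ — the standard quadratic-weight form.  Gradient ascent
starts from the all-ones vector with an adaptive step (halved after an
objective decrease, grown 5% otherwise); convergence is declared when the
objective improves by less than 1e−6 over five consecutive iterations.
Defaults: $\sigma = 1$ on standardized features, $\lambda = 1/n$; the
source study states neither, so both are exposed and logged.

A consequence of the quadratic parameterization worth knowing: when a
feature is duplicated, the optimum splits the *squared* weight between
the copies ($w_1^2 + w_2^2 = w_{\text{single}}^2$, verified numerically),
so raw weights of redundant features shrink by $\sqrt 2$, not 2.

**Leakage control.** By default NCA is refit inside every cross-validation
training fold, and the top-k subset is re-selected per fold.  The source
study appears to have fit NCA once on all data before cross-validating;
that optimistic variant is available as `paper_mode` / `refit = FALSE`
and is labelled in every report it produces.  Features below 2% of the
maximum weight can be regarded as irrelevant, but the primary mechanism is
the explicit top-k sweep (`accuracy_vs_k()`), with k = 16 as the default
subset size in the classification grid (the published best-SVM subset
size).

## 7. Classification

Stratified five-fold cross-validation from a seeded shuffle; fold
membership is a pure function of (seed, row order).  Standardization and
feature selection are fit on training folds only.  Classifiers:

* **K-NN**: k = 5, Euclidean distance; distance ties break by training-row
  order and vote ties by the lowest class index — fully deterministic,
  which is why the package implements the vote itself rather than calling
  a library routine with randomized tie-breaking.
* **LDA**: shared-covariance discriminant via `MASS::lda`; an in-package
  ridge-regularized discriminant takes over if the covariance is exactly
  singular, and the fallback is flagged in the fitted model.
* **SVM**: RBF kernel via `e1071::svm`, C = 1, γ = 1/p on standardized
  features; both logged and configurable.  The source study does not print
  its SVM hyperparameters.

All held-out predictions are pooled into a single confusion matrix
(micro pooling); accuracy, sensitivity and specificity are computed from
it, with per-fold accuracies reported alongside.  The positive class
defaults to CNP and is recorded in every report — the published abstract
numbers are consistent with this mapping through the reconstructed
confusion matrix (TP = 16, FN = 2, FP = 4, TN = 18).  The published
curvilinear K-NN row (80.00 / 83.33 / 78.94) is *not* jointly consistent
with any pooled 40-sample matrix; the acceptance suite asserts this
inconsistency instead of reverse-engineering an unknown pooling scheme.

## 8. Statistics

Group comparisons use the pooled-variance two-sided Student's t-test
(df = nₐ + n_b − 2); the degenerate zero-variance case returns p = 1 for
equal means and p = 0 otherwise.  Normality screening is
Kolmogorov–Smirnov with the Lilliefors correction (`nortest::lillie.test`),
because the reference normal's parameters are estimated from the sample
and the naive KS null would be anti-conservative.  No multiple-testing
correction is applied across bands and metrics by default, mirroring the
source analysis; a Bonferroni flag exists in the run configuration for
users who want it.

## 9. Numerical choices, problem sizes, limitations

* Tolerances: graph metrics match oracles to 1e−9; NCA convergence 1e−6;
  degenerate MSC (0/0 bins) is defined as 0.
* Test problem sizes: unit tests use 3–6 subjects per group and 4–6 s
  trials; the acceptance suite runs the full default cohort (40 subjects,
  3 trials, 10 s) plus a 600-s coherence-recovery pair, 200 random graphs
  and 1000 null t-tests.
* The planted group effect is intentionally strong (standardized effects
  of several σ on delta MSC), so cohort-level accuracies near 100% on the
  curvilinear task say nothing about attainable accuracy on real data —
  only that the pipeline recovers a known effect and stays at chance where
  none exists.
* The t-test decision in the network comparison assumes approximate
  normality of node-averaged metrics; the KS screen is available but not
  automatically gating.
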