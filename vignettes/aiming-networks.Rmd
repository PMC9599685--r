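---
title: "Event-locked EEG networks in the shot-preparation window: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-locked EEG networks in the shot-preparation window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimnet)
```

## What the pipeline computes

`aimnet` analyses multichannel EEG recorded while marksmen hold their aim,
time-locked to each shot. The chain is: zero-phase FIR band-pass filtering
of the continuous signal; individual-alpha-frequency (IAF) estimation from
eyes-closed resting EEG and IAF-anchored band division; event-locked
epoching (−3..0 s aiming window, −4..−3 s baseline); peak-to-peak artifact
rejection; weighted phase lag index (WPLI) connectivity per band, subject
and condition, with the event-related change rate ERWPLI = (WPLI − R)/R
against the baseline matrix R; weighted, unthresholded graph metrics; and
nonparametric group statistics (Wilcoxon rank-sum contrasts, Spearman
correlations with shooting scores, Benjamini–Hochberg FDR).

Because shooter-EEG datasets are typically not public, the package's first
module is a cohort simulator with known ground truth. Everything the later
stages claim to measure — coupling, its condition effects, the IAF, the
artifact process, the score–network link — is planted by the generator, so
the pipeline's statistical behaviour can be verified rather than assumed.

## The signal model of the simulator

Each channel carries `1/f^alpha` Gaussian background noise (`alpha = 1`,
SD 10 µV — a typical resting-EEG magnitude). Planted couplings inject one
shared narrow-band Gaussian oscillator per channel pair, band-limited to
the subject's own theta/alpha/beta band; the copy in the second channel is
delayed by `lag/(2*pi*f0)` seconds (`f0` the band centre), so the pair has
a constant non-zero phase lag and its ground-truth WPLI is analytically
predictable (→ 1 as the oscillator dominates the in-band background). A
zero-lag broadband common source, mixed into every channel with random
gains, serves as a volume-conduction surrogate: it must *not* produce
connectivity, and tests verify it does not. The eyes-closed resting
segment adds a narrow-band oscillation at the subject's true IAF on O1, Oz
and O2 (15 µV), which makes the occipital spectral peak recoverable on the
0.5 Hz analysis grid. Artifact transients are 200 ms Hann bumps of 500 µV
peak on one random channel of a contaminated trial — unambiguous against
the ~10 µV background and detectable by broadband peak-to-peak screening.

Ring scores take values in {0, 5..10} (shots below ring 5 count as
misses). Subject-level mean scores per condition follow a Gaussian copula
against the subject's latent coupling level `u`, so the rank correlation
between score and any coupling-driven network feature is controlled by
a single `rho` parameter. Because the miss rule (rounded scores below 5
count as 0) biases the mean of a discretized normal downwards, the
generator inverts that bias numerically so realized ring-score averages
match the configured condition means. Default per-condition score means
and SDs
(8.02 ± 0.76 control, 8.00 ± 0.81 noise, 5.38 ± 1.56 weak light) reflect
the shooting-performance levels of a skilled cohort under these
conditions, including the marked drop under weak light.

What the generator does *not* emulate: realistic head-model mixing
(the common source has random gains, not a lead field), eye-blink or EMG
waveform morphology, non-stationarity across the session, or
within-subject trial-to-trial coupling dynamics. Passing tests therefore
demonstrate the estimators' correctness and the workflow's calibration,
not robustness to every physiological artifact of real recordings.

## Preprocessing choices

* **Filtering.** Hamming-window FIR design (order 1000 by default at
  1000 Hz) applied forward and backward, since any phase distortion would
  bias phase-synchrony estimates. The per-channel mean is subtracted
  before filtering: with a 0.1 Hz low edge and practical orders, DC is
  otherwise under-attenuated. The broadband 0.1–50 Hz pass precedes band
  division; each analysis band lies inside it, so skipping the broadband
  stage (supported for speed on synthetic data) leaves band-limited
  results unchanged.
* **Epoching** is index-exact: trial *t* starts at `event_t + start`
  seconds and reconstructing a trial from the continuous array reproduces
  it bit for bit. A −3..0 s window at 1000 Hz gives exactly 3000 samples.
* **Artifact rejection** uses a per-trial peak-to-peak threshold (150 µV
  default) on the *broadband* epochs — low-frequency transients would be
  invisible after beta-band filtering — and the retained trial set is
  shared by all bands, mirroring the single trial dimension of the
  preprocessed data tensor. The criterion is a deterministic surrogate
  for manual/ICA cleaning and is flagged in every report.
* **IAF estimation** uses Welch averaging (2 s Hann segments, 50 %
  overlap) to obtain the 0.5 Hz grid with variance reduction, averages
  O1/Oz/O2 power, and takes the 8–12 Hz argmax; ties break to the lowest
  frequency for determinism. A maximum that is not a strict interior
  local peak triggers a warning and is flagged as a fallback, never
  silently accepted. Band edges: theta `[IAF−6, IAF−3]`, alpha
  `[IAF−2, IAF+2]`, beta `[IAF+3, 30]` Hz; 30 Hz is the conventional
  beta ceiling, consistent with a 40 Hz acquisition low-pass.

## Connectivity choices

The analytic signal comes from the FFT Hilbert recipe per trial and
channel; 10 % of samples are discarded at *each* end (the retained length
is `floor(n(1 − 2·0.10))`), where circularity distorts instantaneous
phase.

Two readings of the expectation in the WPLI ratio are implemented.
`"within_trial"` computes one WPLI per trial and averages trial values;
`"pooled"` (the default) pools all trials' retained samples into a single
expectation. The package defaults to pooling because the per-trial ratio
has a positive small-sample bias of order `1/sqrt(n_eff)` (`n_eff` the
number of effectively independent in-band samples per trial) that trial
averaging cannot remove: at 60 trials of 2.4 s beta-band data the
within-trial estimate of two *independent* channels sits near 0.15–0.18,
which would defeat the estimator's zero-lag insensitivity in practice,
while the pooled estimate is ~0.03. Both modes are exposed; all
comparative statistics are unaffected by the choice of a common mode
because both groups use the same estimator.

ERWPLI divides elementwise by the baseline matrix; entries below a floor
of `1e-6` are floored and reported (the ratio is undefined at R = 0).
Baseline epochs undergo the same artifact rejection as aiming epochs.

## Graph-metric conventions

Connectivity matrices enter the network stage unthresholded — every
pairwise weight is an edge. Weighted clustering uses the Onnela
geometric-mean-of-triangles form with max-weight normalisation; path
metrics use inverse-weight edge lengths (`1/w`), with unreachable pairs
excluded from the characteristic path length (their count is reported)
and contributing zero to efficiency. Local efficiency of a node is the
global efficiency of the subgraph induced on its neighbours. Eigenvector
centrality is the leading eigenvector of the raw weight matrix
(Perron convention, unit Euclidean norm) computed by power iteration to
relative tolerance 1e-10; the iteration runs on the matrix shifted by a
positive diagonal constant, which leaves eigenvectors untouched but
breaks the ±lambda symmetry of bipartite graphs that would otherwise
stall convergence. Disconnected graphs use the dominant component with a
warning. All five metrics are validated against independent brute-force
oracles (min-plus distance closure, exhaustive path enumeration on tiny
graphs, dense eigendecomposition, literal triple loops).

## Statistical choices

The Kolmogorov–Smirnov screen tests against a normal with the sample's
own moments and is reported only — the contrast tests are always
nonparametric, which is the conservative choice when normality fails for
some features. Rank-sum tests are two-sided, exact by enumeration when
`n_a + n_b <= 12` without ties, otherwise normally approximated with tie
and continuity corrections. The contrasts are unpaired by default even though the emulated design is
within-subject — the unpaired form matches the emulated workflow and is
what the calibration tests certify; the more powerful paired signed-rank
alternative is available via `paired = TRUE` in the comparison functions. Spearman p-values use the
t-approximation with n − 2 degrees of freedom. FDR is Benjamini–Hochberg,
applied per family — all features of one type within one band and one
contrast; outputs carry both raw and adjusted p-values.

## Problem sizes used in the tests

The estimator oracles run at the native design scale (1000 Hz, 3000
sample epochs, 60 trials). The simulation-based calibration and recovery
checks run at a reduced scale chosen to keep the suite fast while leaving
the statistical questions intact: 200 Hz sampling (beta tops out at
30 Hz, so the Nyquist margin is ample), 20 trials per condition, 20 s
eyes-closed rest, with 20 seeds × 10 subjects per arm for null
calibration and 10 seeds × 30 subjects per arm for effect and correlation
recovery. At this scale the no-effect pipeline yields essentially zero
FDR-significant edges (bound: 5 % of 435), the planted ΔWPLI ≈ 0.2
temporal-pair effect is recovered with the correct sign in ≥ 80 % of
seeds, and the planted rho = 0.6 score correlation is detected in ≥ 70 %
with the mean estimate attenuated slightly below 0.6 (the network feature
is a noisy proxy of the latent the copula acts on).

## Known limitations

* The artifact criterion is amplitude-only; real pipelines combine
  visual inspection or ICA with such thresholds.
* WPLI is undirected; no directed (phase-slope, Granger) measures are
  provided, and debiased WPLI variants are out of scope.
* Absolute weighted-metric values depend on normalisation conventions;
  comparisons and rank correlations are convention-invariant, which is
  why validation rests on oracles rather than on published group means.
* The simulator's stationarity and simple mixing mean that
  generalisation to real recordings should be established per dataset.
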