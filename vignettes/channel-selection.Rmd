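---
title: "Ranking EEG channels for biometric identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking EEG channels for biometric identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An EEG-based identification system assigns a short recording epoch to one of
a set of enrolled subjects. Dense montages make such systems impractical, so
the question this package addresses is: *which channels carry the
identifying information, and how few of them suffice?* The answer is built
in four stages: per-epoch feature extraction in the beta band, relevance
ordering of the features, conversion of orderings into per-channel scores,
and cross-validated re-classification on nested channel subsets.

```{r, eval = FALSE}
library(eegchsel)
ev <- run_pipeline("results/", method = "pca", seed = 7)
plot(ev)
```

## Features

All features are computed per 2-second epoch on beta-band (13--30 Hz)
signals, after per-channel mean subtraction and a broadband 5--40 Hz FIR
pass.

**Band power (PS).** One scalar per channel: the multitaper power spectral
density, averaged over the frequency bins inside the band. The tapers are
discrete prolate spheroidal sequences with time-half-bandwidth product
$NW = 2$ and $K = 3$ tapers, a standard low-variance choice for 256-sample
epochs; at 128 Hz this gives a spectral bandwidth of $\pm 1$ Hz. The
feature is band-averaged (not per-bin) because one scalar per channel per
epoch is what the downstream table requires.

**Asymmetry index (AI).** For each left/right mirror electrode pair,
$\mathrm{AI} = \ln(P_{\mathrm{left}} / P_{\mathrm{right}})$, using the same
per-epoch band powers as the PS features. The montage stores every pair as
(left, right) so the left hemisphere is always the numerator. AI is exactly
antisymmetric under swapping and invariant to a common gain.

**Phase-locking value (PLV).** For each unordered channel pair,
$\mathrm{PLV} = |\,\overline{e^{i(\theta_a(t) - \theta_b(t))}}\,|$, the
modulus of the within-epoch time average of the unit phase-difference
phasor; $\theta$ is the phase of the analytic signal (frequency-domain
Hilbert transform) of the beta-filtered epoch. This is the standard
single-trial PLV, which yields one value per pair per epoch and hence a
per-epoch feature, consistent with the epochs-by-features table the rest
of the pipeline consumes; the alternative of averaging across epochs at
fixed time would give a single value per pair per recording and no
per-epoch features. The leading and trailing 5% of samples are excluded
from the average to suppress transform edge artifacts.

For an $n$-channel montage with $p$ mirror pairs the universe is
$n + p + n(n-1)/2$ features: 112 for the 14-channel consumer layout
(14 PS + 7 AI + 91 PLV), 2107 for the 64-channel 10-10 layout
(64 + 27 + 2016). Restricting to a channel subset keeps exactly the
features whose supporting channels all survive, so subset feature counts
obey the same identity.

## Relevance ordering

Two interchangeable backends order each feature group (PS, AI, PLV
separately) from most to least relevant.

**PCA.** Columns are z-scored, the principal components of the group
submatrix are computed, and features are sorted by decreasing absolute
loading on the first component. Z-scoring makes the decomposition a
correlation-matrix PCA, so "relevance" means participation in the dominant
mode of co-variation rather than raw variance; loading signs are
meaningless and only magnitudes are used. Only the first component drives
the ordering even where it retains a modest share of the group variance;
later components are kept as diagnostics
(`explained_variance_curve()`). Zero-variance columns cannot be z-scored;
they are dropped from the decomposition with a warning and assigned the
lowest positions. Loading ties are broken by canonical catalog order, so
the ordering is deterministic.

**Wilcoxon signed-rank.** For every unordered pair of subjects (all
$\binom{S}{2}$ pairs; 78 for 13 subjects), each feature is tested with a
paired signed-rank test. The signed-rank test requires paired samples and
no natural pairing exists between two subjects' epochs, so epochs are
matched by index after truncating both subjects to the common epoch count;
because the generator (and the assumed acquisition protocol) makes epochs
exchangeable within subject, the index pairing is as good as any. Within
each test the group's features are sorted by ascending $p$-value. The
per-test positions are aggregated across all pairwise tests by modal rank
— the position a feature occupies most often — with ties broken by better
mean rank and then canonical order. After aggregation every feature holds
exactly one position, mirroring the PCA path, so both backends feed the
scorer identically. The $p$-values use the normal approximation with tie
correction and continuity correction; with 40 paired epochs per test the
approximation is accurate, and the implementation is verified against
`stats::wilcox.test` in the test suite.

## Channel scores

An ordering of a group of $f_j$ features assigns position values
$P_i = f_j$ (most relevant) down to $1$. Each feature contributes the
weight

$$W = k_j \frac{P_i}{f_j}$$

to every channel it involves (one channel for PS, both for AI and PLV),
and a channel's score is the sum of its weights:

$$\mathrm{Score}_{ch} = \sum_i W_{ch,i,j}.$$

The group constants default to $k_{PS} = 2$, $k_{AI} = 1$,
$k_{PLV} = 1.2$, reflecting the relative contribution of each feature
family to identification accuracy; they are plain configuration
(`scoring_config()`) and scale the scores homogeneously, so doubling all
three changes no ranking. Channels are sorted by descending score, ties
broken by montage order.

## Evaluation

`crossval_classify()` runs stratified 10-fold cross-validation of an
RBF-kernel SVM at the epoch level. Per outer fold, features are
standardized with the training split's means and standard deviations only;
the box constraint and kernel scale are selected from the grid
$C \in \{0.1, 1, 10, 100\}$,
$\gamma \in \{0.01, 0.1, 1, 10\}/d$ ($d$ = feature count) by inner 3-fold
macro precision on the training split. Reported metrics are
macro-averaged precision, recall and F1 (classes never predicted
contribute zero precision) and the generalized multiclass Matthews
correlation coefficient, each as per-fold mean ± sd in percent.
`incremental_evaluation()` repeats this for nested subsets of the top-$n$
ranked channels, $n$ from all channels down to 1.

Cross-validation is deliberately at the epoch level: epochs of one subject
appear in both training and validation folds. That matches the
identification protocol being modelled (enrolled subjects, within-session
recognition) but means the metrics say nothing about cross-session
generalization; the report manifest carries this caveat.

## The synthetic generator

`simulate_eeg()` exists so that every stage is testable without data
downloads. Its defaults mirror the acquisition geometry of a 13-subject
study with a 14-channel consumer headset: 80 s per subject at 128 Hz, so
2-s epoching yields 40 epochs per subject and a 520 × 112 feature table.
Four channels (T8, F8, FC6, FC5 by default) are "informative": each
subject gets an individual beta frequency in 15--28 Hz, per-channel
amplitudes $A = A_0(1 + c\,U(0,1))$ drawn once per subject (amplitude
contrast $c$, default 1, on a common amplitude $A_0 = 6\,\mu V$), and
per-channel phase lags; a mixing weight $\kappa \in [0,1]$ (default 0.8)
blends a shared per-subject source with channel-independent oscillations,
planting phase locking among the informative channels. Non-informative
channels oscillate independently with parameters drawn per 2-s block from
one population distribution, so their epochs are exchangeable across
subjects. On top sit $1/f$ background ($4\,\mu V$) and white sensor noise
($2\,\mu V$). All draws derive from one seed; recordings are bit-identical
given the seed.

The generator emulates the *statistical* structure the method needs —
subject-specific band power, asymmetry and phase coupling against a
common background — and nothing physiological: no volume conduction, no
artifacts, no non-stationarity, no session effects. Passing tests
therefore demonstrate that the pipeline recovers planted structure under
realistic SNR, not that real recordings would reach any particular
accuracy.

## Numerical choices

* **FIR filtering**: windowed-sinc (Hamming) design via `signal::fir1`,
  transition width 2 Hz, order $\lceil 3.3 f_s / 2 \rceil$ rounded up to
  even; applied forward-backward for zero phase. The forward-backward pass
  is computed in the frequency domain (convolution with the filter's
  autocorrelation, reflected end padding), which matches
  `signal::filtfilt` to ~1e-9 away from the ends and is an order of
  magnitude faster on long recordings.
* **Slepian tapers**: computed from the standard symmetric tridiagonal
  eigenproblem and cached per epoch length; orthonormality, spectral
  concentration and agreement with an independent implementation are
  tested.
* **Degenerate inputs**: constant channels make the instantaneous phase
  undefined and non-positive band powers make AI undefined; both raise
  errors pointing at the degenerate input rather than propagating NaNs.
  Epochs with amplitudes beyond an optional threshold can be rejected at
  segmentation; the default keeps all epochs so that pipelines are
  deterministic and the 40-epochs-per-subject geometry is preserved.
* **EDF I/O**: 16-bit storage against a symmetric physical range just
  covering each channel's extrema bounds the round-trip error by
  range/2^15. Vendor label decorations ("EEG Fc5.") are normalized before
  montage matching.
* **Ties**: every ordering, ranking and fold assignment has an explicit
  deterministic tie-break (canonical catalog or montage order, or the
  seeded shuffle), so identical inputs and seeds reproduce identical
  outputs byte for byte.

## Problem sizes used by the test suite

The property suites run at sizes chosen to give stable statistics on a
single CPU: planted-channel recovery uses 50 independent simulations of
the full 13-subject geometry for each ranking backend; the comparison of
the recovered 4-channel classifier against a random non-informative
4-channel baseline uses 11 simulations (median reported) with a reduced
tuning grid ($C \in \{1, 10\}$, $\gamma \in \{0.1, 1\}/d$); the
label-permutation null uses 12 shuffles of the 520-epoch table with a
single-point grid ($C = 1$, $\gamma = 1/d$), since chance-level behaviour
does not depend on tuning. Unit tests use smaller montages and shorter
recordings where the property under test allows it.

## Limitations

* Scores depend on the $k_j$ constants; the package treats them as given
  configuration and provides no procedure to re-derive them from data.
* The Wilcoxon aggregation ("modal rank, then mean rank") is one of
  several defensible readings of rank aggregation across pairwise tests;
  alternatives (mean-rank only, Borda) would differ in edge cases.
* Only one analysis band is supported per run; cross-band feature fusion
  is out of scope, as are other connectivity metrics (coherence, PLI),
  re-referencing schemes and artifact-subspace removal.
* Epoch-level cross-validation overstates deployable accuracy whenever
  enrollment and use are separated in time; treat the subset curves as
  relative comparisons between channel sets, not absolute performance.
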