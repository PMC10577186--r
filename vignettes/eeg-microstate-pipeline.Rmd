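---
title: "Resting-state EEG microstates for disorders of consciousness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstates for disorders of consciousness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmicrostates)
```

## The analysis this package implements

Resting-state EEG alternates between brief (~60-120 ms) periods during
which the scalp potential topography stays quasi-stable — *microstates*,
conventionally grouped into four classes A-D. After ischemic stroke,
patients with a disorder of consciousness (DOC, clinically a Glasgow Coma
Scale below 13) show altered microstate dynamics relative to awake stroke
patients: longer B and C states, a shorter D state, a less complex
transition syntax, and a higher delta/alpha power ratio (DAR). This
package implements the full analysis chain that quantifies those
contrasts and feeds them to a classifier, together with a synthetic
cohort generator, because clinical EEG of this kind cannot be shared and
every stage therefore has to be testable against planted ground truth.

The chain is: band-pass filtering and common average referencing; Welch
spectra and the DAR; microstate segmentation (GFP peaks, polarity-invariant
modified k-means, back-fitting, temporal smoothing); temporal features and
global explained variance; Lempel-Ziv complexity of the transition string;
two-group statistics including a permutation TANOVA; and cross-validated
RBF-SVM classification of four canonical feature sets.

## Models and definitions

**Global field power.** For an average-referenced sample
$u(t) \in \mathbb{R}^n$ over $n$ electrodes,
$\mathrm{GFP}(t) = \sqrt{\tfrac1n \sum_i (u_i(t) - \bar u(t))^2}$,
the population SD across electrodes. GFP peaks are moments of high
topographic signal-to-noise; only peak maps enter clustering. Peaks are
strict local maxima, thinned to a 10 ms minimum separation; peaks above
mean(GFP) + 2 SD(GFP) are discarded as likely artifacts (an `absolute`
mode, 2 SD as a hard threshold, is also provided since the convention is
ambiguous); if more than `n_maps` (default 2000) remain, a seeded uniform
subsample is taken.

**Modified k-means.** Microstate clustering ignores polarity: a map and
its negation are the same state. Assignment maximizes the squared spatial
correlation (Pearson across channels; on average-referenced unit-norm
vectors this is a squared dot product), and each prototype is re-estimated
as the dominant eigenvector of $\sum_{v \in \text{cluster}} x_v x_v^\top$
— the direction maximizing summed squared correlation, which is
sign-indifferent by construction. The algorithm restarts from random map
subsets (`n_restarts`) and keeps the solution with the highest explained
variance. Convergence is declared at a relative explained-variance change
below `tol` (1e-6), capped at `max_iter` (100) iterations per restart.
Empty clusters are reseeded from the worst-fitted map. All ties break to
the lowest class index, making every stage deterministic given its seed.

**Model order.** `choose_k()` computes, per candidate $k$, the
cross-validation criterion
$\mathrm{CV}(k) = \hat\sigma^2_{\text{resid}} \left(\frac{n-1}{n-1-k}\right)^2$
(to minimize) and the Krzanowski-Lai index from successive within-cluster
dispersions (to maximize; undefined at the range edges, hence at least
three candidate values). The two criteria can disagree, and no canonical
combination exists, so the package's rule is: among candidates whose CV
lies within 5% of the CV minimum, take the one with the largest KL; if KL
is undefined there (structureless data), take the smallest such $k$. On
well-separated planted prototypes this selects the planted $k$; on pure
noise it falls back to small $k$, which the test suite pins as a
regression rather than a theoretical claim.

**Back-fitting and smoothing.** Every sample gets the label of the
prototype with maximal $|$spatial correlation$|$; zero-GFP samples inherit
the previous label (class 1 at the start). Smoothing then enforces a
minimum run duration (30 ms): every maximal run shorter than the floor is
dissolved, its samples handed to the two neighboring runs. The spec of
record for this package hands each sample to the neighbor whose prototype
correlates better with it, under a contiguity constraint: the run splits
at the point maximizing the total absolute correlation of the left part
with the left neighbor and the right part with the right neighbor. An
unconstrained sample-by-sample reassignment can interleave labels and
re-create sub-minimum runs indefinitely; the contiguous split keeps the
same objective and strictly reduces the run count each step, so
termination is guaranteed. Edge runs take their only neighbor's label.

**Temporal features.** Per class: mean duration (ms), occurrence (runs/s),
coverage (% of samples), and GEV
$= 100 \sum_{t: L(t)=k} (\mathrm{GFP}(t)\, r_{t,k})^2 / \sum_t \mathrm{GFP}(t)^2$
with $r_{t,k}$ the spatial correlation with the assigned prototype. The
identity coverage$/100$ = occurrence $\times$ duration$/1000$ holds exactly
on any label sequence, and the suite asserts it as an invariant. A class
absent after smoothing reports zeros with a warning rather than NaN.

**Transition complexity.** The label sequence is collapsed to its
transition string (BBBCCAADDB becomes BCADB) and parsed with the LZ76
exhaustive-history scheme: the phrase count over the first $N = 300$
symbols is the complexity. No normalization is applied; values are
compared only at fixed $N$. The main routine is a linear scan; the test
suite cross-validates it against an independent brute-force substring
parser on a thousand random strings, and checks the monotonicity-in-length
and alphabet bounds that the measure must satisfy.

**Spectra.** Welch PSD with a Hanning taper, 2.048 s windows, 50% overlap.
At a 100 Hz sampling rate 2.048 s is 204.8 samples, which is not
realizable; the window is `round()`ed to 205 samples with `nfft = 205`,
reproducing the ~0.488 Hz resolution the protocol reports. Segments are
mean-detrended; densities are one-sided. Band power is the bin sum of the
channel-averaged spectrum over the closed interval, and
DAR = delta(1-4 Hz) / alpha(8-13 Hz), averaging over channels *before*
taking the ratio.

**Group statistics.** Welch's t (and its reconstruction from printed
mean/SD/n summaries, pooled or unpooled), Mann-Whitney U reported as
min(U1, U2) with a tie- and continuity-corrected normal z, Pearson
chi-square on 2x2 tables with optional Yates correction, mean-centered
Levene, and a permutation TANOVA: subject maps are average-referenced and
scaled to unit GFP, the statistic is the GFP of the difference between
group mean maps, and the null comes from label shuffles with the add-one
p-value convention. All tests are two-sided; no multiplicity correction
is applied across the feature battery, mirroring the reporting convention
of the clinical literature this models — a caveat, not an endorsement.

**Classification.** Feature Set 1 is the 12 temporal features (duration,
occurrence, coverage for A-D); Sets 2 and 3 add DAR and LZC respectively;
Set 4 adds both. Stratified 10-fold cross-validation wraps an RBF-SVM with
$C = 1$. Standardization and PCA (retaining 95% of variance by default)
are fitted inside each training fold only — the protocol this follows does
not describe its leakage control, so the package defaults to the
conservative choice. The kernel width is $\gamma = 1/(d \cdot
\mathrm{Var}(X_{\text{train}}))$, the scale-free heuristic. Sensitivity is
TP/(TP+FN) on the DOC-positive class. The headline AUC pools decision
scores across folds; per-fold AUCs are reported where the held-out fold
contains both classes.

## The synthetic cohort generator

No EEG of this clinical population is available, so the generator is a
first-class, tested module rather than a fixture. One recording is

$$x(t) = a(t)\, m_{s(t)} \cdot 10\,\mu V + \text{delta component} +
  \text{alpha component} + \varepsilon(t)$$

* $s(t)$: a semi-Markov state sequence over $k = 4$ planted classes. Run
  lengths are gamma-distributed (shape 4, so SD = mean/2, all-positive)
  with per-state planted means, resampled above the 30 ms smoothing floor
  so smoothing cannot erase planted structure by construction. The
  truncation biases realized means upward by a few percent, which sits
  well inside the 15% recovery tolerance the generator is designed to.
* $m_k$: planted topographies built from low-order polynomial gradients
  plus a random Gaussian bump over the 10-20 electrode coordinates —
  dipolar-looking without a head model — average-referenced, unit-norm.
  The documented contract caps pairwise $|$correlation$|$ at 0.7, but the
  default draw uses 0.5: near-0.7 pairs are legal yet genuinely
  non-identifiable by polarity-invariant clustering at the noise levels
  the generator targets (the wrong partition can score *higher* explained
  variance than the truth), and the generator is specified to produce
  recoverable structure.
* $a(t)$: rectified band-limited (4-13 Hz) noise plus a 0.3 floor,
  rescaled to unit mean — GFP then fluctuates and peaks at realistic
  rates without ever vanishing entirely.
* Spectral components: band-limited (1-4 and 8-13 Hz) noise waveforms,
  each riding a fixed random spatial pattern that is projected out of the
  span of the planted prototypes — so planted band power can never
  masquerade as a fifth topography — with variances splitting a fixed 25%
  of the clean-signal power in proportion to the delta/alpha targets.
  Raising the delta target therefore strictly raises the measured DAR.
* $\varepsilon$: white sensor noise, SD expressed as a fraction of the
  clean-signal RMS.

Cohorts derive per-subject seeds from one master seed. All subjects (both
groups) share a single prototype seed: microstate topographies are
empirically consistent across people, and it is the *temporal* statistics
that separate groups — per-subject prototype draws would make group-level
clustering meaningless. The group presets plant the reported clinical
contrast: awake — durations (A, B, C, D) = (83.6, 68.3, 81.0, 87.7) ms,
uniform transitions, delta/alpha target 3.7; DOC — (92.5, 76.8, 90.2,
84.6) ms, a cycle-biased transition matrix (70% chance of following a
fixed A->B->C->D cycle before row normalization, lowering transition
complexity), delta/alpha target 5.3.

What the generator does *not* emulate: ocular/muscle artifacts (artifact
removal by ICA is out of scope — the pipeline accepts artifact-free input
by contract), volume conduction from a head model, non-stationarity
across the recording, or inter-subject topographic variability. Passing
recovery tests therefore demonstrate correctness of the estimation chain
under the stated model, not robustness to clinical artifacts.

## Numerical choices

* **Filtering.** Hamming-windowed FIR, order from the 3.3/transition-width
  rule with the transition at 25% of the low edge (order 1320 for 1 Hz at
  100 Hz). Zero phase is obtained by applying the symmetric kernel
  centered, via FFT convolution with zero-padded edges, which compensates
  the group delay exactly while keeping the designed magnitude response
  (a forward-backward pass would square it); recordings must span three
  filter lengths so edge transients are negligible. The notch is a +/-1 Hz
  FIR band-stop; at a 100 Hz sampling rate a 50 Hz notch sits exactly at
  Nyquist and inside the stop band of the 1-30 Hz band-pass, so the
  pipeline skips it there (the low-level filter function still rejects it
  as a precondition violation).
* **Epoching.** When a recording is longer than the 60 s analysis epoch,
  the first window is used; the protocol this models does not state its
  selection rule, and a deterministic choice keeps runs reproducible.
* **Peak subsampling with fewer peaks than requested** keeps all peaks and
  warns: a 60 s epoch at 100 Hz yields roughly 1000-1200 admissible GFP
  peaks, so the nominal 2000 maps of the protocol (which had >=10 min of
  recording) is not always reachable.
* **Degenerate inputs.** Zero-GFP samples carry the previous label;
  all-zero maps are rejected; two constant equal samples give t = 0,
  p = 1; identical groups give TANOVA p = 1 by the add-one convention.
* **LZC prefix.** Sequences shorter than $N$ raise an error by default
  (complexity grows with length, so shorter strings are not comparable);
  `on_short = "use_full"` opts out explicitly, and the pipeline uses it
  so that short test cohorts run end to end.

## Problem sizes

The test suite and the acceptance script size their simulations to keep a
single-CPU run in the tens of seconds while leaving the conclusions
stable: parameter recovery uses two 60 s recordings (noise 0.5 and 0.3)
with 1000 peak maps and 30 restarts; calibration uses 1000 null draws of
n = 28 per group; the end-to-end cohort uses 14 subjects per group at
60 s with 1000 maps and 30 restarts; oracle cross-validation of LZ76 uses
1000 random strings of length 300. These are the package's choices of
demonstration scale; the estimators themselves have no size limits beyond
memory.

## Known limitations

* Absolute LZC levels depend on the parsing variant; this package commits
  to LZ76 exhaustive parsing, so its raw counts are comparable only with
  implementations of the same variant.
* The two-level group clustering (subject prototypes, then clustering of
  pooled subject prototypes) is one defensible aggregation among several;
  published protocols rarely state theirs.
* The canonical A-D templates are qualitative geometric stand-ins over
  the 10-20 layout, used only to give recovered prototypes stable names;
  they are not empirical grand-average maps.
* The classifier reports fold-averaged metrics on cohorts of modest size;
  with 10 folds over 28 subjects the per-fold test sets are small and the
  metrics correspondingly coarse (steps of 1/2 to 1/3 per fold).
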