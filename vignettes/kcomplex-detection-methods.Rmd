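---
title: "Methods: multi-domain feature detection of k-complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-domain feature detection of k-complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
conventions behind `kcdetect`, in the spirit of a methods section: what the
pipeline assumes, which knobs matter, and what the synthetic validation does
and does not establish about clinical data.

## The detection problem

A k-complex is a well-delineated negative sharp wave immediately followed by
a slower positive wave, lasting roughly 0.5–2 s, standing out of the N2
sleep background. Treating detection as window classification converts a
continuous scoring task into a supervised learning one: every 0.5 s window
(stepped by 0.1 s, i.e. 80% overlap) becomes an instance, labeled positive
when at least half of its samples lie inside an expert-scored event. The
0.5 s window matches the minimum event duration, so a window is never longer
than the shortest event it must capture; the 0.1 s step gives 5 votes across
a minimal event, at the cost of strong inter-window correlation (see
*Limitations*).

The labeling rule itself (≥ 50% of window samples inside a single event,
half-open intervals on both sides) is a package choice — annotation-based
corpora specify events, not window labels. `min_overlap` is exposed;
lowering it trades boundary false negatives for diluted positives. Labels
are deterministic and monotone in the threshold.

## Preprocessing

Filtering uses a Butterworth band-pass, 0.5–30 Hz, overall order 4 (two
pole pairs), applied causally by default: the clinical convention states an
order, not a phase behavior, and the causal form is what a real-time
implementation would use. A `zero_phase` flag switches to forward–backward
filtering, which cancels phase distortion but squares the magnitude
response (effective order 8): at 50 Hz the causal realization attenuates to
|H| ≈ 0.25, the zero-phase one to ≈ 0.06. Out-of-band leakage at this level
is immaterial for the features, which are dominated by delta-band energy.

## The 22 features

**Time domain (f1–f12).** Defined verbatim in the detection-literature
convention rather than the textbook one, and the divergences are
deliberate: the standard deviation uses the N−1 denominator; skewness and
kurtosis are plain moment ratios scaled by that standard deviation, with
kurtosis keeping its +3 offset; the crest, impulse and margin factors use
peak-to-peak (max − min) numerators, which for a biphasic wave respond to
both lobes at once; the zero-crossing rate takes sgn(0) = +1; the time
centroid `Σ n·x(n)/Σ x(n)` uses 1-based indices. Degenerate windows return
0 with a flag rather than NaN — a constant window zeroes skewness/kurtosis,
a zero-sum window zeroes the centroid — so feature matrices stay finite and
selectors never see missing values.

**Spectral domain (f13–f19).** The spectrum is the one-sided energy
spectrum E(k) = |X(k)|², scaled so Parseval's identity `Σ E(k) = Σ x(n)²`
holds exactly (interior bins doubled; DC and Nyquist not). Whether "the"
spectrum means amplitude or energy is a genuine ambiguity in this
literature; energy was adopted, and the Parseval property pins the scaling
down testably. DC is included by default (`include_dc`), no taper is
applied by default (the 0.5 Hz high-pass has already removed the mean;
windowing is available behind the spectrum's own interface if needed). The
band-energy-ratio band defaults to 0.5–4 Hz because k-complex energy is
delta-band; the roll-off constant defaults to 0.85, the upper end of its
conventional 0.6–0.85 range, which better separates broadband background
from concentrated transients. The bandwidth about the centroid uses the
absolute (not squared) energy-weighted deviation. The flatness measure
floors zero bins at `1e-12 · max E(k)` before the geometric mean.

**Chaotic domain (f20–f22).** All three are slope estimates of log–log
scaling laws whose defining r → 0 limits are meaningless on 100-sample
windows; what is computable is the slope over a finite scaling region, and
the package returns the fit diagnostics (`r²`, fit range) alongside every
estimate.

* *Correlation dimension*: Grassberger–Procaccia on the delay-embedded
  window, Chebyshev metric. Embedding dimension m = 3 by default; the delay
  is the first zero crossing of the autocorrelation, capped at N/8 — both
  standard heuristics, exposed in the configuration since no values are
  canonical for 0.5 s EEG windows. C(r) counts distinct pairs with distance
  strictly below r. The radius grid is 16 log-spaced radii between the 2nd
  and 30th percentiles of the pairwise distances: near the median distance
  the correlation integral saturates and drags the fitted slope below the
  true dimension on two-dimensional test sets, while below the 2nd
  percentile too few pairs remain for stable counts. The scaling region is
  the contiguous window of ≥ 5 grid points maximizing fit r² (ties to the
  wider window).
* *Box dimension*: the window's graph (index vs. value) is normalized to
  the unit square — making the estimate exactly invariant under positive
  affine maps of the signal — resampled densely (4096 points) along the
  polyline so boxes crossed between samples are counted, and boxes of side
  1/2 … 1/32 are counted on dyadic grids. A constant window normalizes to a
  horizontal line (dimension ≈ 1) and is flagged.
* *Generalized dimension*: same box occupancy, aggregated as
  `(1/(q−1)) log Σ pᵢ^q` with q = 2 by default — the member of the Rényi
  family that pairs with the correlation dimension and avoids the q = 1
  singularity (q = 1 is rejected with a pointer to the information-dimension
  limit, which is out of scope). At q = 0 the formula reduces exactly to
  box counting, which the tests exploit as a consistency check; D_q is
  non-increasing in q.

## Feature selection

Continuous features are discretized by equal-frequency binning (10 bins by
default) before any entropy or consistency computation; bin count trades
pattern resolution against sparsity and is exposed everywhere it is used.

* **ReliefF** uses k = 10 nearest hits and misses under range-normalized
  Manhattan distance, sampling all instances by default. Because raw
  ReliefF weights rarely approach the conventional 0.7 selection threshold,
  the threshold is applied to min–max normalized weights; this makes "0.7"
  meaningful but also guarantees at least one selected feature — a
  documented divergence from a literal raw-weight reading.
* **CFS** scores subsets by `k·r̄_fl / √(k + k(k−1)·r̄_ff)` on absolute
  Pearson correlations of standardized features (point-biserial against the
  binary label is Pearson, so no special case), searched best-first with a
  stale cap of 5 non-improving expansions. No thresholds by construction.
* **Subset search** minimizes either the inconsistency rate or a seeded
  internal 5-fold CV error of the configured classifier. Enumeration of all
  2^F − 1 subsets is exact up to 15 features; 2^22 evaluations is not a
  realistic desk computation, so above the cap the search falls back to
  best-first with the same measure, announced via a message. Ties break
  toward smaller subsets, then column order, making results invariant to
  feature permutation.
* **INTERACT** ranks by symmetrical uncertainty and scans backward from the
  weakest feature, dropping any whose consistency contribution is ≤ 1e-4
  (no canonical value exists; the threshold is exposed). The backward order
  is what lets individually weak but jointly informative pairs (XOR-style
  interactions) survive.

The inconsistency rate is monotone non-increasing under feature addition —
the property that makes backward elimination sound — and this is enforced
by property tests against a brute-force grouping oracle.

## Detection and evaluation

Classifiers are deliberately plain: LDA, linear SVM (cost 1), and a CART
decision tree (Gini, default pruning). Features are standardized with
training-fold statistics only, and when a selector is configured it is
refit inside every training fold — the test fold can never influence
selection, which the suite verifies with a recording spy selector.

Cross-validation is stratified 5-fold under a master seed. Metrics come
from the pooled per-fold confusion matrix formulas: sensitivity,
specificity, accuracy, F-score with tunable β (β > 1 weights recall of true
k-complexes), and Cohen's kappa in the standard `(p_o − p_e)/(1 − p_e)`
form. Division-by-zero branches (empty margins, p_e = 1) return 0 with a
flag instead of NaN. The screening report supplies per-feature Spearman ρ
against the label, one-way ANOVA F and p (for two classes, F equals the
squared pooled t statistic, used as a test oracle), and the Fisher
criterion J1 = tr(S_w⁻¹ S_m) with both scatter matrices normalized by n so
values are comparable across sample sizes; a singular S_w receives a
1e-8-scaled ridge with a warning.

## The synthetic generator: what it emulates, what it does not

The generator's defaults are the package's reference study conditions: a
15-minute, 200 Hz recording carrying 60 non-overlapping events of 0.5–2 s,
with event peak amplitude 8 times the background standard deviation
(15 µV background → ≈ 120 µV events, typical of scored k-complexes against
quiet N2 background). The background is an AR(2) resonance peaked near
2 Hz mixed with 30% white noise, band-limited to 0.5–30 Hz — delta-dominant
like N2 sleep. The k-complex template is two raised-cosine lobes (negative
40% of the duration, then positive) with a 1.5:1 amplitude ratio, chosen so
the lobe areas cancel exactly; 13 Hz spindle-like distractor bursts can be
injected optionally. Events are placed by rejection sampling with a 0.5 s
refractory gap and 1 s edge margins.

What this establishes: that the feature definitions carry the separability
they claim (positive windows show higher short energy and deeper negative
means), that selectors recover compact subsets, and that the full pipeline
is correct, deterministic and leak-free end-to-end. What it does not
establish: performance on clinical recordings. Real N2 sleep contains
artifacts, slow-wave (N3) look-alikes, spindles superimposed *on*
k-complexes, inter-scorer disagreement, and non-stationary background —
none of which the generator models. Synthetic results bound software
correctness, not clinical accuracy.

Class imbalance (≈ 8% positive windows under the reference conditions) is
handled by seeded 1:1 random undersampling of negatives before selection
and cross-validation, the common practice in this detection literature;
the ratio is configurable and `NULL` disables balancing. Reported
specificity consequently refers to the retained negatives.

## Problem sizes and determinism

The test suite validates formulas exhaustively where cheap (every confusion
matrix up to n = 6), by randomized oracle comparison where not (500 random
matrices for the inconsistency rate; 100 random problems with up to 10
features for subset-search optimality against bitmask enumeration), and
runs the full reference pipeline (≈ 9000 windows × 22 features) for the
end-to-end and byte-level reproducibility checks — sizes chosen to keep the
whole suite in the minutes range while leaving the search spaces
non-trivial. Every stochastic step (generator, undersampling, folds,
ReliefF sampling) draws from an explicit seed; identical configuration and
seed reproduce reports byte-for-byte, which is asserted, not assumed.

## Known limitations

* Overlapping windows are correlated instances; pooled (not
  subject-grouped) cross-validation on them is optimistic relative to
  event-level, cross-subject evaluation. A grouped-fold variant is the
  natural extension point.
* Window-level metrics are not event-level metrics: one detected window
  inside a 2 s event scores differently than detecting the event once.
* The exhaustive-search cap means the 22-feature consistency search is
  heuristic (best-first); optimality is only guaranteed at ≤ 15 features.
* Fractal estimates on 100-sample windows are rough summaries with large
  variance; they are features, not physical dimension measurements, and
  their fit diagnostics should be consulted before interpreting them.
* EDF support is minimal (16-bit, equal-rate channels, 1 s records, no
  EDF+ annotations channel) — sufficient for polysomnography exports and
  the package's fixtures, not a general EDF library.
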