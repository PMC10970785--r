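---
title: "Building and validating ambient-MS tissue classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating ambient-MS tissue classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tissueprint)
```

Handheld ambient mass spectrometry turns a probe touch into a molecular
fingerprint: a few 1-s time-of-flight scans whose lipid-dominated peak
pattern is characteristic of the tissue being sampled. Classifying such
fingerprints is statistically treacherous — supervised projections
separate anything, including noise — so the modeling workflow matters at
least as much as the model. This vignette documents the model this package
implements, its assumptions, the tunable parameters, the synthetic data it
is validated on, and the design decisions taken where practice is not
settled.

## The data model

The unit data point is the **sampling event**: one probe interrogation,
recorded as a short series of scans, belonging to one **specimen** (an
independent piece of tissue) and one **class** (the diagnostic label).
Events from the same specimen are statistically dependent — they share that
specimen's biology — which drives two design rules used throughout:

* each sampling event is one row of the fingerprint matrix (scans are
  summed, not treated as replicates of independent information), and
* data splits for validation are performed at the specimen level by
  default, so no specimen contributes to both training and test sides.

Peak lists are collapsed into fixed-width m/z bins (default 100 mDa,
half-open, left-closed, anchored at the range minimum, with the floor
convention for assignment). Binning at this width tolerates the mass drift
of time-of-flight analyzers without lock-mass correction and is lossy by
design; nothing downstream assumes sub-bin mass accuracy.

### Quality control

QC is label-blind and runs on raw (pre-normalization) intensities. The
defaults — at least three 1-s scans and a summed event total ion intensity
strictly above 10^3 counts — encode the minimal-signal rule found workable
for soft-tissue fingerprints. The intensity floor is interpreted per event
(summed over scans); a per-scan reading is possible via
`qc_criteria(min_total_intensity = ...)` against single-scan aggregates.
Optional criteria (required non-zero bins, replicate cosine floor, CV
ceiling) exist because "expected peaks present" and repeatability checks
are instrument-side practices; whether expected peaks should be global or
class-specific is left to the user through `required_bins` rather than
guessed. Every attempt is logged so the duty cycle — the fraction of
attempts producing a usable (and later, a classified) result — is honest.

Normalization follows QC: total-ion-current scaling by default, with
non-zero-median and median-fold-change (+ `log(value + 1e-9)`; the
pseudocount avoids `log(0)` without visibly distorting non-zero bins) as
alternatives.

## The model: PCA-LDA with component rules

The classifier is principal-component reduction followed by Fisher linear
discriminant analysis in the score space. Two counting rules guard against
overfitting:

* **PC cap**: `n_pc = min(floor(n_events / 5), n_events − n_classes,
  n_bins)` — approximately one-fifth of the number of data points, an
  empirical ceiling reflecting the number of truly resolvable features in
  these spectra. Reported uses of the one-fifth rule differ by one or two
  components in how they round; this package implements the floor-and-cap
  form above and makes no attempt to reproduce any particular rounding.
* **LD dimensions**: classes minus one, the rank of the between-class
  scatter.

Within-class scatter is pooled across classes for axis estimation (the
standard Fisher formulation); per-class covariances in LD space are kept
separate for scoring, because cluster shape carries real information when
classes have unequal intra-class variance. Axes are solved as the
generalized symmetric eigenproblem via Cholesky whitening, with a tiny
relative ridge (`1e-8 × trace/p`) on the pooled scatter for invertibility
near the degrees-of-freedom limit, and a sign convention (largest-magnitude
coefficient positive) for reproducible plots. Data are centered but not
per-bin scaled before PCA — TIC-normalized intensities share units, and
variance-scaling would inflate empty-bin noise; scaling remains available
as an option.

`scree()` exposes the explained-variance fractions; `loading_ranks()`
ranks bins by the Euclidean norm, over LD axes, of their composite
(PCA∘LD) projection weight — the loading-plot quantity that feeds feature
shortlists. Ties are broken by ascending bin index.

## Classification as probabilities, not verdicts

A projected spectrum receives squared Mahalanobis distances to every class
centroid under that class's covariance, converted to posteriors
proportional to `prior × |Σ|^{−1/2} exp(−d²/2)` and normalized in log
space (distant points therefore never underflow to 0/0). Three outcomes:

* **classified** when the best posterior reaches the threshold (default
  0.95 — no published value exists; the threshold trades duty cycle for
  accuracy and is fully configurable);
* **unclassifiable** when confidence is insufficient: a no-call, excluded
  from accuracy, counted in the duty cycle;
* **outlier** when even the nearest class is beyond the chi-square
  quantile (default 0.999, dof = number of LD axes): the spectrum resembles
  none of the competing classes — e.g. a spectrum dominated by a process
  the model was never trained on, such as cautery smoke — and no
  prediction is issued.

Centroid-based scoring is the reference choice here; distance-to-boundary
scoring is a recognized alternative when cluster shapes differ wildly, and
is deliberately not guessed at.

One behavior deserves emphasis: when models are fitted at the full
one-fifth cap, the LD axes partially fit within-class estimation noise, so
training-set covariances *understate* the spread of events from unseen
specimens and absolute chi-square envelopes become aggressive. For this
reason cross-validation (below) disables the outlier envelope by default
(`outlier_quantile = 1`) and measures the raw model; posterior calibration
is studied separately on compact models (see the threshold benchmark),
where a Scree-guided 25-component model keeps posteriors calibrated while
matching the large model's accuracy.

## The validation battery

`crossvalidate()` runs repeated splits (default 25) holding out 20% of
specimens per class (`round(f × specimens)`, at least 1), refits under the
component rules, and aggregates a confusion matrix (classified events
only), accuracy-over-classified, duty cycle, per-class
sensitivity/specificity, Cohen's kappa, one-vs-rest AUROC from posterior
scores with midrank tie handling, and per-specimen concordance (agreement
with each specimen's modal call, specimens with ≥ 2 classified events).
Repeated random splits stand in for exhaustive leave-p-out, which is
combinatorially infeasible; an event-level split (`split_level = "event"`)
exists only to demonstrate the optimism that specimen leakage produces.

Two chance-level controls calibrate expectations:

* **mixed-class permutation** (`permute_labels_mixed()`): pseudo-classes
  composed of equal shares (within one event; remainders seeded) of every
  true class, processed with the same component counts — the "this is what
  no signal looks like" companion every separation plot should have;
* **pseudo-classes** (`pseudo_classes()`): one homogeneous class split
  into k near-equal groups (exact equality is not forced; published splits
  were not exactly equal either).

Both must cross-validate at ~1/k; the package's acceptance battery asserts
this within a 99% binomial interval whose n is the number of distinct
events tested (repeats reuse events, so pooled prediction counts would
overstate the information).

### Learning curves and the overfitting demonstration

`learning_curve()` subsamples the data at usage fractions 0.1–1.0 and
cross-validates each subset, re-deriving the PC cap per fraction
(`adaptive_fifth`) or freezing it (`fixed`). Subsampling has two modes:
`usage_level = "specimen"` answers the sample-size question (how many
independent specimens suffice?) and requires ≥ 2 specimens per class at the
smallest fraction; `usage_level = "event"` subsamples events across all
specimens — the classic data-usage curve, and the only feasible reading
when a study has ~10 specimens per class. Each curve point averages a
fresh subsample and split per repeat, which stabilizes consecutive-point
differences enough for saturation to be assessed.

On the distinct-classes conditions the adaptive event-usage curve starts
high and is flat beyond 40% usage (the saturation a sufficient sample size
shows). Freezing the cap at its full-data value reproduces the *low-usage
optimism* of overfitting when splits are event-level: at 10% usage the cap
equals the training count, the model memorizes specimen positions, and
dependent events on the test side reward it. The package reproduces this
inflation. The classic *mid-usage dip with later recovery* does not emerge
under this generator: once the component set spans all specimen
directions, event-split accuracy stays at ceiling regardless of how
oversized the cap is. The dip appears to require non-stationary structure
(instrument drift, day effects, heterogeneous acquisition batches) that
the generator deliberately omits; with specimen-aware splits the
inflation cannot occur at all, because there is nothing to leak. Both
points are why specimen-aware splitting is the default everywhere else.

## Synthetic study conditions

`generate_dataset()` draws binned fingerprints hierarchically:

```
event fingerprint = baseline + class offset + specimen effect + event noise,
clipped at zero
```

with a lognormal per-dataset baseline, sparse class offsets (10% of bins
per class, disjoint across classes when possible; `class_separation` is
the offset norm in units of event-level SD), i.i.d. normal specimen
effects (`specimen_sd`) and event noise (`event_sd`), seeded scan weights
summing each event exactly, degraded events (2 scans, ~500 total counts)
at a configured rate, and an optional high-intensity contaminant bin in a
subset of classes. Truncated-normal additive noise is the simplest model
matching intensity semantics; it is a stand-in, not a claim about
instrument physics — no quantitative noise model for these spectra is
published.

The `distinct_classes` preset fixes the conditions the validation story is
told under: 3 classes × 10 specimens × 44 events (1320 events, a typical
three-tissue demonstration scale), 1000 bins, `class_separation = 21`,
`specimen_sd = 3`, `event_sd = 1`, 5% poor-quality events. The ratios
encode the regime these instruments occupy with very distinct tissues:
inter-class variance far above intra-class variance, and sampling events
far more repeatable than specimens are similar. Under these conditions the
specimen-aware 20% leave-out accuracy lands in the mid-to-high 90s with
errors dominated by occasional wayward specimens — which is also why
probability thresholding on the big model cannot buy accuracy here
(confidently wrong whole specimens evade any threshold), while on the
compact 25-PC model thresholding trades a fraction of a percent of duty
cycle for a small accuracy gain. What passing these tests shows is that
the workflow's statistics behave as designed on data with exactly the
assumed structure; it does not show robustness to drift, batch effects,
isotope structure, adducts, or any other real-data feature the generator
omits.

Other presets: `pseudo_class_single_tissue` (one homogeneous class, 410
events, for the pseudo-class control), `contaminated` (moderate biological
separation plus a 30-count exogenous feature in one class at bin 150 — the
false-discovery scenario), and `heterogeneous` (specimen variance at the
scale of class separation, where honest accuracy is poor).

## Sparse refitting and artifact exclusion

`select_top_features()` shortlists the top-100 loading bins;
`feature_annotations()` records offline identification outcomes
(`identified_biological` / `unidentified` / `flagged_artifact` — the
package deliberately does not automate identification, which happens by
MS/MS and database work outside fingerprinting); `apply_annotations()`
filters (drop flagged, or keep identified-only); `fit_sparse()` reruns the
identical pipeline on the retained bins with the cap re-derived. The
benchmark battery operationalizes the cautionary tale: a contaminant that
is the top-ranked classifier makes the full model collapse by ~33
percentage points when the contaminant is absent at test time, while the
sparse model built after flagging it moves by well under one point.

## Numerical choices, degenerate inputs, limitations

* Ridges: `1e-8 × trace/p` on pooled within-class scatter; `1e-6 ×
  trace/n_ld` on each per-class LD covariance (so Mahalanobis is always
  defined). Both are relative and configurable.
* Ties: arg-max class calls break ties in ascending class-label order;
  loading ranks break ties by ascending bin index; modal concordance calls
  break ties alphabetically.
* Degenerate inputs that raise: all-zero spectra under TIC or
  non-zero-median; LDA with one class or a class of one event; splits with
  a single specimen in a class; pseudo-class splits leaving singleton
  classes; non-positive-definite covariances in `mahalanobis_sq()`.
* Seeds: every stochastic function takes a seed, derives per-repeat
  sub-seeds internally, and restores the caller's RNG state.
* Problem sizes in the benchmark battery (12 CV repeats, 5 learning-curve
  repeats per fraction, 50 cross-check instances per quantity, 20 threshold
  seeds, 1000 split-hygiene draws) are the package's documented choices,
  sized so the full battery completes in about a minute on one CPU.
* Out of scope by design: peak picking from profile data, lock-mass
  correction, isotope/adduct simulation, non-linear learners, MS/MS
  identification, and multi-site reproducibility logistics.
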