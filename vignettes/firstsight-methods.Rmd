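---
title: "Decoding first percepts from wedge-binned contrast energy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding first percepts from wedge-binned contrast energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(firstsight)
```

## The scientific question

In breaking continuous flash suppression (bCFS), two images presented to
one eye compete against a dynamic mask shown to the other; the image a
participant reports first indexes prioritized access to visual awareness.
When the two images are faces with different emotional expressions, a
class-level bias (say, happy before angry) admits two very different
explanations: the *emotional content* of the expressions, or plain
low-level differences in spatial-frequency and orientation contrast
between the photographs. `firstsight` implements, end to end, the
analysis strategy that separates these explanations:

1. describe each image by the contrast energy in 24 spatial-frequency
   (SF) x 16 orientation wedges of its Fourier magnitude spectrum
   (384 features per image, 768 per two-image trial);
2. decode, with an ensemble of feature-selecting SVMs, (a) which side is
   reported first from the 768 trial features and (b) which expression an
   image carries from its 384 features;
3. compare the two analyses' per-feature weights by correlation;
4. test the predictive value of emotional content directly, by
   cross-validated prediction of each trial's outcome from the training
   folds' class biases alone, against a permutation null.

Because the face photographs and behavioral data that motivated this
design are not redistributable, the package ships a synthetic-data module
that emulates the study conditions with full experimental control: images
are synthesized *in the feature space itself*, and responses are generated
by a known rule, so every downstream claim can be checked against ground
truth.

## The feature grid

`build_grid()` partitions the discrete Fourier plane of an N x N image
into SF bands times orientation wedges. Every non-DC coefficient with
radius between 1 cycle/image and Nyquist (N/2) belongs to exactly one
wedge; conjugate-symmetric pairs share a wedge because orientation is
taken modulo 180 deg. A wedge's feature value is the *sum of magnitudes*
(not power) of its coefficients, so features are non-negative, add up to
the total included magnitude, and scale linearly with image contrast.

Two conventions deserve emphasis:

* **Propagation direction vs. image orientation.** A coefficient on the
  horizontal Fourier axis describes left-right luminance change and hence
  *vertical* contours in the image. `horizontal_axis_wedges()` selects the
  orientation bin centered on 0 deg for exactly this reason: "vertical
  image contrast" lives there.
* **SF band edges.** Nominal band edges are log-spaced from 1 to Nyquist
  (octave-like spacing matches visual-system practice). On an integer
  frequency lattice, however, the radii below ~3 cycles/image are sparse
  (1, sqrt 2, 2, sqrt 5, ...), and several low-frequency log bands would
  contain no coefficient at all. The builder therefore snaps each interior
  edge to the geometric midpoint between two consecutive *achievable*
  radii. This keeps the spacing log-like at high SF, devolves to
  one-radius-per-band at the sparse low end, and guarantees every band is
  populated. Individual *wedges* (band x orientation cells) can still be
  empty at low SF - those features are constantly zero and are excluded
  from model fitting by the zero-variance guard.

No window is applied before the transform; the image mean is subtracted
(removing DC). There is deliberately no per-image energy normalization:
the stimuli the design emulates were presented at fixed contrast, and raw
contrast energy is the quantity of interest.

## Synthetic stimuli

`make_wedge_noise_image()` constructs an image directly in the Fourier
domain: per-wedge target energies (a base level, plus an optional additive
class signature, times a per-wedge lognormal identity jitter) are spread
uniformly over each wedge's coefficients, phases are taken from the FFT of
white noise (guaranteeing Hermitian symmetry), and the inverse transform
is rescaled around mean luminance 0.5. Feature extraction of a synthetic
image therefore returns its jittered targets *exactly*, up to one global
contrast factor - the extraction-synthesis round trip is tested to
floating-point accuracy rather than statistically.

Two details matter for scientific hygiene:

* **One contrast scale for the whole set.** The rescale factor is computed
  analytically (via Parseval) from the spec's base energies, not from each
  image's realized pixel range. Rescaling per image would inject a shared
  per-image factor into *every* wedge; any quantity driven by any wedge
  would then leak into all 384 features, and both decoders would "find"
  signal everywhere. With a common scale, the realized Michelson contrast
  instead varies a little from image to image (mean ~ 0.17, SD ~ 0.015 at
  the default target 0.176, chosen to sit on the emulated study's contrast
  scale), as unmanipulated photographs do.
* **Energy-neutral expression signatures.** `expression_delta_spec()`
  gives each class (happy / angry / neutral) an offset in its own
  orientation band (vertical Fourier axis, 45 deg, 135 deg) over two
  mid-range SF bands, and *removes the same total energy* uniformly from
  the remaining wedges. Classes thus differ in where their contrast
  energy sits, not in how much they have - mirroring stimuli presented at
  equal maximum Michelson contrast - and the contrast rescale cannot turn
  total-energy differences into an artifactual class signal.

The default signature magnitude (0.35, about twice the identity jitter
SD of 0.15) makes an expression reliably decodable from its wedge *set*
while no single wedge separates the classes on its own, the way real
expression information is spread over several frequency components.

Trials follow the six-condition design (HA-HA, HA-NE, HA-AN, AN-NE,
AN-AN, NE-NE) with 48 trials per condition by default (288 total),
left/right class placement exactly counterbalanced, and two distinct
identities on the two sides. Responses come from `response_model()`:
P(left first) is a lapse-mixed logistic in the difference of summed
"driver wedge" energy between the two images. This generative rule is the
package's own stand-in - the emulated study decodes behavior but never
models it - and encodes its conclusion (contrast energy in specific
wedges, not emotional content, determines which image wins) as a samplable
mechanism. The energy difference is divided by its SD over the trial set
by default, making `beta` unit-free. Reaction times are stored as
lognormal draws (median ~ 3 s) purely for schema completeness; no analysis
touches them.

## The ensemble decoder

`run_ensemble()` implements the pooled feature-selection design. Over
stratified folds, four model families are trained per fold:

* **filter**: nested top-k sets from a chi-square ranking (each feature
  quantile-binned, default 10 bins; scored against class by the
  contingency chi-square);
* **wrapper**: forward stepwise inclusion maximizing inner-CV linear-SVM
  accuracy, diversified across models by stratified 70% subsampling of
  the training split. Subsampling (rather than bootstrap resampling) is
  used because bootstrap duplicates land on both sides of the inner CV
  split and systematically reward noise features. The stepwise search
  scans the top chi-square-ranked candidates (`wrapper_pool`), which
  bounds its cost without changing its performance-driven semantics;
* **random**: sizes matched to the filter models, features drawn uniformly
  from those that vary in the training split;
* **pseudo-random**: same sizes, drawn from features *unused* by the
  fold's filter and wrapper selections (falling back to wrapper-unused
  only when that pool runs dry).

Every model is a linear-kernel SVM, cost 1, one-vs-one for three classes,
with training-split standardization; its performance is the fraction of
correct predictions on the fold's held-out split. For each fold x method,
`control_reps` control models re-run the method's selection on
label-shuffled training data, train on the shuffled labels, and are scored
against the *true* test labels - a pool of chance performances (1000 at
the defaults: 10 folds x 4 methods x 25) that preserves the selection
machinery in the null.

`score_relevance()` turns the pool into per-feature inferences. A
feature's **weight** is the mean performance of the real models that
contained it (zero if never tested). Features tested few times have
noisier weights, so the significance threshold is matched to the tested
count m: `null_resamples` means of m control draws form a matched null,
and the feature is significant only when its weight exceeds that null's
*maximum* (empirical p below 1/`null_resamples`).

### What the null does and does not control

Development of the synthetic testbed made two limitations of
mean-performance relevance weights explicit, and both are worth knowing
about when interpreting real data:

* **Hitchhiking.** A noise feature co-selected into a model that also
  contains informative features inherits that model's high performance.
  The matched null corrects for *how often* a feature was tested, not for
  *whose company it kept*. Hitchhiking is diluted only by testing breadth:
  when each feature also appears in many signal-free (random /
  pseudo-random) models, its mean regresses to chance. The significant set
  is therefore trustworthy in proportion to how sparse the informative
  set is relative to the feature space.
* **In-dataset flukes.** With finitely many images, some noise feature
  will correlate with the labels at the dataset level; that correlation
  is shared by training and test folds, so it supports genuine
  generalization *within the dataset* and no label-shuffled control can
  represent it. Its magnitude shrinks with sample size and grows with the
  log of the feature count. Model-multiplicity is the lever: with few
  models per method the matched thresholds stay near the control-pool
  maximum and flukes stay below them, at the cost of statistical power
  for true signals.

The package's own validation embraces this trade-off explicitly: the
planted-signal recovery runs (sparse strong signatures, 10 models per
method) probe sensitivity plus purity, while the type-I runs (shuffled
labels, 2 models per method, a 10,000-resample null) probe specificity.
The scales used by the packaged checks - a 12 x 8 x 64 px grid with 45
images per class for recovery and the awareness analyses, an 8 x 4 x 64 px
grid for the null runs, 4 outer folds, wrapper capped at 2 inclusions,
filter sizes within the signature size - were chosen once as desk-scale
study conditions and are fixed; the full 24 x 16 x 128 default grid and
the 10 x 4 x {10, 25} ensemble structure are exercised by the structural
checks and remain the defaults for real analyses.

## Weight correlations

`split_sides()` separates the 2 x 384 concatenated layout into per-wedge
left and right weight vectors; `average_sides()` averages them;
`correlate_weights()` reports Pearson r with the exact t-transform p
(n - 2 df). Features never tested by any model carry weight zero and are
excluded by default (`untested_either`); a `subset` mode restricts the
correlation to a supplied feature set, e.g. the features significant in
the expression analysis. Parametric p-values are used because the
analyses this mirrors report parametric-style r/p pairs; at the small n
of a wedge grid they should be read as descriptive.

## Behavioral statistics

`first_percept_fractions()` computes, per subject and class, the fraction
of different-class trials containing that class in which it was reported
first; with a balanced design the three fractions of one subject average
to exactly 0.5. `friedman_rank_test()` and `wilcoxon_signed_rank()`
implement the group-level tests with midranks, tie-corrected variances
and (for Wilcoxon) discarded zero differences and no continuity
correction - the two-tailed p convention is used throughout since the
emulated analyses do not state one. Both are validated in the test suite
against exhaustive permutation oracles (all within-row orderings for
Friedman; all 2^8 sign assignments for Wilcoxon) and against the stats
package implementations.

`bias_cv_predict()` is the content-only predictor: stratified 10-fold CV
in which each test trial of a class pair is predicted by the majority
first-percept class of that pair in the training folds (exact 50/50
training bias falls back to a seeded coin flip; a pair absent from a
training split falls back to the global training bias, with a warning).
Its permutation null re-shuffles response sides across trials *within
condition* and recomputes the entire cross-validated accuracy; p =
(1 + #{perm >= obs}) / (n_perm + 1) with 10,000 permutations by default.
`fixed_class_predict()` is the one-sided variant (always predict a given
class), with the same permutation scheme. Shuffling responses within
condition - rather than shuffling outcome labels - is essential: each
trial's outcome class is determined by its response side *and* its
left/right placement, and only the response side is exchangeable under
the null.

## Reproducibility model

Every function that consumes randomness takes a seed, and all internal
streams are derived from it by name (`derive_seed(seed, "synthesis")`,
...), so any stage can be re-run in isolation and `run_all()` output is
byte-identical across runs of the same config. Config objects round-trip
through YAML; stimuli are written as 8-bit grayscale PNG, trial tables and
feature/relevance tables as CSV, and summary results as JSON.

## Known limitations

* Synthetic images are phase-randomized noise with controlled wedge
  energies: they share the emulated stimuli's feature-space statistics but
  none of their spatial structure (no faces, no local features, no
  phase alignment). Passing tests show the *pipeline* recovers what was
  planted under the stated conditions; they cannot show that real faces
  are driven by the same wedges.
* The relevance criterion inherits the hitchhiking and in-dataset-fluke
  caveats above; on real data its significant sets should be read as
  "features repeatedly associated with successful decoding", not as
  causally isolated drivers.
* The wrapper explores a chi-square-screened candidate pool; features
  informative only in combination with others (and individually
  uninformative by chi-square) can escape both the filter and the wrapper.
* Reaction times are generated but never analyzed, by design.
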