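---
title: "Methods: SHG collagen quantification with shgfib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SHG collagen quantification with shgfib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shgfib)
```

`shgfib` quantifies hepatic collagen fibrosis from second-harmonic generation
(SHG) photon-count images. This vignette explains the models and procedures
the package implements, the parameters that matter, what the synthetic
phantom generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The data model

An image is a non-negative integer matrix of photon counts, nominally
100 × 100 pixels at 10 µm per pixel; the absolute count scale is arbitrary
(it depends on detector gating). Pixels are indexed 0-based from the top-left
corner, rows increasing downward. All orientation angles are measured
counter-clockwise *as seen on screen* from the +x (column) axis, i.e. with
the y axis taken to point toward decreasing row index; fiber orientations are
undirected, so angles live on the period-180° orientation circle.

A study is a manifest of images tagged with a diet group (C, A, S, AS), an
animal id, and a binary fibrosis label (1 = visible collagen fibers).

## Feature extraction

The **noise threshold** of an image is one tenth of the maximum magnitude of
its 2-D discrete Fourier transform. Magnitudes are normalized by the pixel
count (`normalized = TRUE`, the default), which makes the DC magnitude equal
to the image mean; because no frequency component of a non-negative image can
exceed the DC component, the threshold is identically `mean(counts)/10`.
This identity is asserted as a property test. The unnormalized convention is
available as a flag; it only rescales the threshold by the pixel count.

**Window features.** A `window_size` × `window_size` square window (default
20, the scale of a few fiber widths) slides with `stride` 1 in both
directions; a 100 × 100 image yields 81 × 81 = 6561 windows, emitted in
row-major order of their top-left corners. On each window's flattened pixel
vector we compute population moments (mean, σ, skewness m₃/σ³, non-excess
kurtosis m₄/σ⁴), the mode of the raw integer counts, the total sum, and
`frac_above`, the fraction of pixels strictly above `factor ×` the *image's*
noise threshold. Conventions the data source leaves open, fixed here once:

* population (not sample) moment denominators; σ = 0 ⇒ skewness and kurtosis
  defined as 0;
* mode over raw integer counts, ties broken toward the smallest value;
* the threshold is computed once per image and shared by its windows (the
  threshold is a property of the image's signal, not of a 400-pixel patch);
* `factor = 0.15` for window-level features ("15 % of the noise threshold")
  and `factor = 1` for image-level features — the two phrasings used for the
  window- and image-level analyses respectively; both are exposed as one
  parameter rather than guessing a single intent.

Image-level features are the same statistics over all pixels, plus the
mean/σ ratio (undefined, and flagged `NA`, for constant images).

## Feature ranking and label validation

`rank_features()` fits a random forest — 100 CART-style trees on bootstrap
resamples, Gini impurity, √p candidate features per split, unlimited depth —
and reports normalized mean-decrease-in-impurity importances. The forest
behind the interface is the **randomForest** package; an independent
implementation (**ranger**) is used in the test suite as a cross-check on the
top of the ranking. Window labels inherit their image's label. The mean/σ
ratio is appended to the seven window statistics before ranking, since it is
one of the image-intensity descriptors the classification stage can use;
zero-variance windows, where the ratio is undefined, are dropped with a
message. No numeric importances exist to recover, so the tests assert
structural facts: importances are a normalized distribution, a single
informative feature dominates a constructed table, permuted labels produce no
spurious dominance.

`shg_kmeans()` is a from-scratch Lloyd iteration, written out because the
procedure itself (not a library call) is the point: Forgy initialization with
k = 2 data points drawn with the seed, nearest-Euclidean-centroid assignment,
centroid-as-mean update, convergence when the largest centroid displacement
falls below `tol = 1e-6` (standardized units; the stopping rule "centroids no
longer change significantly" needs a number, and 1e-6 is far below any
feature scale of interest) or after `max_iter = 500`. An emptied cluster is
reseeded to the point farthest from its previous centroid. Features are
z-score standardized by default because the sum feature is ~10⁴ × larger than
the fraction feature; the flag is exposed. Inertia is tracked every iteration
and asserted non-increasing; on fixed seeds the final inertia matches
`stats::kmeans` within 1 %. `label_agreement()` scores an assignment against
labels under the better of the two cluster↔label mappings.

## The classifier

A single sigmoid neuron p = σ(w·x + b) on one feature — the image-level
`frac_above`, which is linearly separable between classes in the phantom
study by construction — is trained by full-batch Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8, bias-corrected) at learning rate 0.05 on the binary cross-entropy
loss. Choices the method description leaves open:

* **Epochs:** 500 full-batch epochs. On standardized separable data the loss
  settles well before that; the training curve is stored in the model.
* **Full-batch vs mini-batch:** full-batch, so the fit is deterministic given
  the data ordering (weights start at zero; no RNG enters training).
* **Standardization:** features are standardized with training-split
  statistics stored in the model; a zero-variance feature is left unscaled
  with a warning (the neuron then cannot use it, which is the correct
  degenerate behavior and keeps the all-constant symmetry case trainable).
* **Loss clipping:** probabilities are clipped to [1e-12, 1 − 1e-12] inside
  the loss only; predictions are never clipped.
* **Decision rule:** hard label 1 iff p > 0.5, strictly, so an uninformative
  p = 0.5 classifies as non-fibrotic.

`kfold_cv()` uses stratified folds (each class shuffled with the seed and
dealt round-robin), the natural choice for a 160/80 class split with k = 20:
every fold holds 8 negatives and 4 positives, and no training split can lose
a class. Plain folds are available by flag. Per-fold confusion matrices are
summed element-wise into the aggregate before computing F1, sensitivity,
specificity and accuracy; metrics with zero denominators are reported as
undefined rather than NaN.

## Fiber orientation

Images the classifier calls fiber-positive are binarized (strictly above a
threshold; the per-image noise threshold by default, an explicit cutoff in
the pipeline — see below) and passed to a Hough transform over a 1°-step
normal-angle grid and 1-px ρ bins. Peak extraction is greedy: take the
highest accumulator cell, refine the line by an iterated principal-axis fit
to its inlier pixels on a shrinking ρ band (3 → 2.5 → 2 px), report it, then
*remove* the inliers' accumulator contributions and apply ±5-cell
non-maximum suppression (θ wraps at 180° with ρ mirrored). The removal step
is essential with fibers rendered several pixels wide: a thick band produces
an accumulator ridge whose tails would otherwise re-trigger as duplicate
lines, and the raw grid argmax alone sits on a near-plateau and can be off by
several grid steps, while the shrinking-band fit suppresses the aliased band
edges that bias rasterized diagonal fibers and recovers centerline
orientations to a fraction of a degree (99 %+ of noise-free single fibers
within 1°). The reported fiber orientation is the normal angle + 90°, mapped
to [0°, 180°).

`min_votes` defaults to 20, half the shortest fiber length of the default
phantom configuration; `max_lines` defaults to 25 per image. Both should be
matched to the expected fiber geometry of real data.

**Relative angles.** Within each image one detected fiber is chosen uniformly
at random as the reference; remaining orientations become signed differences
wrapped to (−90°, 90°]. The reference is drawn once per image and relative
angles are pooled across a group's images before histogramming (bins tiling
(−90°, 90°], default 5°). Drawing the reference per image rather than per
group reflects that no orientation frame is shared across tissue sections.

**Width.** Two readings of "angular distribution width" are implemented. The
default is the period-180° circular standard deviation, computed on doubled
angles — invariant to the reference shift and well-defined for tight
distributions. The alternative is the FWHM of the (3-bin smoothed) angular
histogram. Both are reported by the pipeline; they measure different things
(≈2.355 σ apart for a normal shape) and neither is treated as a recoverable
quantity from real data, where "width" is not precisely defined.

**Pooling caveat.** Pooling *relative* angles across images adds the
reference fibers' own sampling noise to the dispersion — for images sharing a
common mean orientation it inflates the circular SD by ≈ √2. The group width
can therefore also be computed from the pooled detected orientations
directly (`pooling = "orientation"`), which is the efficient estimator
whenever a common deposition axis exists; phantom-recovery tests use it. For
real tissue, where sections have no shared frame, only the relative pooling
(the default) is meaningful, and its √2 inflation is shared by all groups so
*comparisons* between groups survive.

## Cohort summaries

The unit of replication is the animal: per animal, the percentage of its
images classified fiber-positive; per group, mean and sample SD (n−1) across
its animals. This is the natural reading of a "mean ± SD per group" table for
a 6-animal design; a per-image bootstrap would understate animal-to-animal
variability.

## The synthetic phantom generator

Phantoms emulate the *statistical* structure the analysis assumes, not SHG
optics (no phase matching, polarization, or forward/backward ratio — pure
intensity phantoms, single plane):

* Background: i.i.d. Poisson counts, rate 0.5 per pixel — a low-photon
  counting regime in which the Fourier noise threshold of a fiber-free image
  (0.05 counts) sits below every photon hit.
* Fibers (fibrotic images only): k ~ Uniform{5..10} straight segments,
  lengths Uniform(40, 70) px, placed uniformly with both endpoints inside the
  image, rendered with a Gaussian transverse profile (σ = 1 px, peak
  amplitude 20 counts) summed over overlapping fibers (no excluded volume),
  rounded and added to the background. Orientations are wrapped-normal on the
  period-180° circle around 90° with cohort-specific dispersion, and every
  rendered orientation is recorded in the manifest as ground truth.
* Cohorts: C/A/S/AS × 6 animals × 10 scans with fibrosis prevalences
  0.08/0.24/0.40/0.62 and angular dispersions 26/24/16/2.8°. Per animal the
  fibrotic image count is ⌊p·m⌋ plus a Bernoulli draw on the fractional part,
  so the expected study composition is 80.4 fibrotic of 240 while the
  across-animal SD stays nonzero. Whether the real 160/80 split was balanced
  or emergent is unknowable from the study description; the generator treats
  it as emergent from the per-group prevalences.

The amplitude/background defaults were chosen from one constraint: the
mean-scaled noise threshold must stay below 1 count for the heaviest
realizable fiber load (10 fibers × 70 px × amplitude 20 gives a mean ≈ 4 and
threshold ≈ 0.4). Then every background photon hit counts as above-threshold
and every rendered fiber pixel clears the threshold, so the fibrotic class's
`frac_above` is the non-fibrotic level *plus* fiber coverage — the two class
distributions cannot overlap. That separability is a designed property of the
phantoms, and it is what makes the perfect cross-validated classification
reproducible; passing it says the pipeline is correct, **not** that real SHG
data are this easy. Real images bring focus drift, intensity inhomogeneity,
curved and branching fibers, and specialist-label noise, none of which the
generator emulates.

For orientation analysis the pipeline binarizes at an explicit cutoff
(default 5 counts ≈ a quarter of the fiber amplitude) rather than the noise
threshold: in the low-count regime the noise threshold sits below single
photons, and a mask containing 40 % background hits defeats line voting. With
the explicit cutoff a background pixel needs ≥ 6 photons (probability ≈ 10⁻⁵
at rate 0.5) to enter the mask.

## Problem sizes used by the test suite

Tests run at sizes chosen for statistical power, not to showcase scale:

* Classification and prevalence recovery use the full default study
  (240 images), the latter averaged over 20 generator seeds and compared to
  the configured prevalences within 3 binomial standard errors.
* The angular-ordering property (widths strictly decreasing C > A > S > AS)
  is evaluated on 50 seeds × 4 cohorts × 150 fibrotic images of 8–12 fibers,
  with group width from pooled detected orientations. The binding contrast is
  26° vs 24°: the circular-SD sampling error is ≈ σ/√(2n), so ≈ 1400 angles
  per group are needed for the per-seed ordering probability to clear 99 %;
  smaller cohorts (or relative-angle pooling, with its √2 inflation) leave
  the ordering a coin flip at that contrast. This power calculation fixed the
  test size before the test was first run.
* Single-fiber Hough recovery uses 200 noise-free phantoms; window-statistics
  oracle equivalence uses 100 random windows against a naive double-loop
  implementation.

## Known limitations

* Straight-fiber model only: no curvilinear tracing, no branching, no fiber
  thickness estimation (fiber diameter is below the optical resolution of the
  imaging this emulates).
* Near-parallel overlapping fibers can merge into one detection (the AS-like
  regime); detection counts per image are therefore biased slightly low,
  which leaves dispersion comparisons intact but makes absolute per-image
  fiber counts unreliable.
* The PNG writer is 8-bit (the underlying library does not write 16-bit
  grayscale); TIFF (16-bit) and plain text carry full depth, and overflow on
  write is an error, never a silent clip.
* K-means is a single initialization per seed (as the validation procedure it
  mirrors); for routine clustering use restarts or `stats::kmeans`.
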