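# shgfib — collagen fibrosis quantification from SHG microscopy images

Second-harmonic generation (SHG) microscopy images collagen directly: the
coherent frequency-doubled signal is dominated by fibrillar collagen, so an
SHG scan of liver tissue maps where collagen fibers are and how they are
oriented. In fatty-liver disease models, both the *amount* of fibrous
collagen (fibrosis) and the *alignment* of the fibers change as disease
progresses. `shgfib` implements a complete, tested analysis pipeline for such
photon-count images, aimed at microscopists and image analysts who want a
reproducible route from raw scans to per-cohort fibrosis statistics:

1. **Statistical features.** A 20 × 20-pixel window slides across each image
   (stride 1) and seven statistics are computed per window on the pixel
   population: mean, standard deviation σ, skewness (third standardized
   moment), kurtosis (fourth standardized moment), mode, total intensity sum,
   and the fraction of pixels above a multiple of the *noise threshold*. The
   noise threshold is one tenth of the maximum magnitude of the image's 2-D
   discrete Fourier transform; with pixel-count normalization that maximum is
   the DC component, so the threshold equals mean intensity / 10.
2. **Feature ranking.** A random forest (Gini impurity, 100 trees, √p
   candidate features per split) ranks the window features, including the
   mean/σ ratio, by normalized mean decrease in impurity.
3. **Label validation.** A from-scratch K-means (k = 2, Forgy initialization,
   ≤ 500 iterations) clusters four image-level features — mean, σ, mode, and
   the above-threshold pixel fraction — to confirm that specialist labels
   match the unsupervised structure.
4. **Classification.** A single sigmoid neuron, p = σ(w·x + b), trained with
   full-batch Adam (learning rate 0.05) on the binary cross-entropy
   −mean[y log p + (1−y) log(1−p)], classifies images as fibrotic (p > 0.5).
   Generalization is estimated by stratified 20-fold cross-validation with
   per-fold confusion matrices summed into one aggregate, from which
   F1 = 2TP/(2TP+FP+FN), sensitivity = TP/(TP+FN) and specificity =
   TN/(TN+FP) are read.
5. **Fiber orientation.** Fiber-positive images are binarized and straight
   fibers detected with a (ρ, θ) Hough transform (greedy peak extraction with
   inlier removal and sub-degree principal-axis refinement). Orientations are
   expressed relative to a randomly chosen reference fiber, pooled per diet
   group, histogrammed, and summarized by an angular distribution width —
   either the period-180° circular standard deviation or the histogram FWHM.
6. **Cohort report.** Per-animal fiber-positive percentages aggregate to
   group mean ± SD tables and a width table.

Because the original microscope data are not redistributable, the package
ships a **synthetic phantom generator** that reproduces the statistical
structure of the study design: 4 diet groups (control C, arsenic A, sucrose
S, arsenic–sucrose AS) × 6 animals × 10 scans = 240 images of 100 × 100
pixels (10 µm/pixel), with group fibrosis prevalences 0.08/0.24/0.40/0.62 and
fiber angular dispersions 26/24/16/2.8°. Every rendered fiber's orientation
is recorded as ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(shgfib)

ds <- generate_dataset(seed = 42)        # default 4-cohort study, 240 images
ds
#> <shg_dataset> 240 images, 4 groups, 80 fibrotic / 160 non-fibrotic

feats <- dataset_features(ds)            # image-level feature table
cv <- kfold_cv(feats$frac_above, feats$label, k = 20, seed = 42)
cv
#> <shg_cv> 20-fold cross-validation (stratified), n = 240
#>   aggregated confusion matrix:
#>               predicted+  predicted-
#>     actual+          80           0
#>     actual-           0         160
#>   F1 1.0000 | sensitivity 1.0000 | specificity 1.0000 | accuracy 1.0000

model <- train_neuron(feats$frac_above, feats$label)
pred <- data.frame(image_id = feats$image_id,
                   predicted = predict(model, feats$frac_above, type = "class"))
group_fiber_percentages(pred, ds$manifest)
#>   C   6.7 ± 5.2%  (6 animals, 4/60 images)
#>   A   23.3 ± 5.2%  (6 animals, 14/60 images)
#>   S   40.0 ± 0.0%  (6 animals, 24/60 images)
#>   AS  63.3 ± 5.2%  (6 animals, 38/60 images)

fiber_orientation_analysis(ds$images, ds$manifest$group, pred$predicted == 1,
                           threshold = 5, pooling = "orientation", seed = 42)
#>  group     width n_angles n_images
#>      C 20.827196       29        4
#>      A 22.027310       92       14
#>      S 17.647262      159       24
#>     AS  3.138467      247       38
```

The classifier separates the two classes perfectly (the synthetic classes are
constructed non-overlapping in the above-threshold fraction), and the
recovered group percentages track the configured prevalences within
animal-level sampling noise. The width column recovers each cohort's angular
dispersion; note that at this cohort size the control group contributes only
a handful of fibrotic images (here 29 fibers), so its width estimate is noisy
— the C/A contrast (26° vs 24°) needs far more fibers to resolve reliably,
which is exactly how the test suite evaluates it (see the vignette).

A full staged run with artifacts on disk:

```r
run_pipeline(NULL, out_dir = "out", seed = 1)   # writes images, CSVs, report
```

or from a shell via the thin wrapper `inst/cli/shgpipe.R`
(`Rscript shgpipe.R run-all --out out --seed 1`).

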