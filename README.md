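# finstripe

Automated species and sex identification of Lake Malawi rock-dwelling
cichlids ("mbuna") from standardized lateral photographs. Closely related
mbuna differ subtly in coloration, melanic stripe pattern and body shape —
differences that defeat non-expert human observers — and `finstripe`
implements a complete image-analysis pipeline that turns each photograph
into a fixed numeric summary, classifies it, and relates the resulting
confusion structure to genetic distance.

The pipeline is aimed at evolutionary biologists and taxonomists working
with large photographic collections of closely related fishes, and at
anyone who needs a reproducible, fully testable reference implementation of
this class of color/stripe/shape classifier.

## What it computes

**Feature extraction.** Each photograph is background-masked (background
pixels held at a magenta sentinel, RGB (255, 0, 255), which every
downstream statistic ignores) and summarized by 48 features:

- 42 color features: the foreground is quantized into its k = 7 dominant
  colors (optimum-palette generation by k-means in RGB space), each
  reported in RGB and HSV, all channels scaled to [0, 1];
- the color ratio n₀/n₁ of the pixel counts of the two most frequent
  colors;
- the Shannon entropy H = −Σᵢ pᵢ log₂ pᵢ of the 8-bit grayscale foreground
  histogram (0–8 bits);
- the Canny edge-pixel count divided by the foreground pixel count, so
  larger fish are comparable with smaller ones;
- counts of straight horizontal, diagonal and vertical segments detected on
  the edge map at 45° angular granularity.

**Feature selection.** Per-feature F-score
F(i) = Σ_c (x̄ᵢ,c − x̄ᵢ)² / Σ_c Var_c(xᵢ),
the ratio of between-class squared mean deviations to the summed
within-class sample variances; features with F ≥ 0.7 (default) are kept.

**Shape.** 17 landmarks per specimen (TPS files) are superimposed by
generalized Procrustes analysis — centering, scaling to unit centroid size,
and rotation-only least-squares alignment to the iterated consensus —
yielding 34 Procrustes coordinates that are appended to the 48 image
features (82 variables in total).

**Classification.** Support vector machine (RBF) or random forest
(mtry = 14, 500 trees), evaluated by repeated random-subsampling
cross-validation: 100 independent unstratified 80/20 train/test splits,
with attribute scaling (and optional selection) fitted on each training
split only. Results are reported as mean ± s.d. accuracy and as a
predicted × actual confusion matrix with per-class accuracies.

**Genetics link.** The confusion matrix is condensed to a symmetric
pairwise misclassification-rate matrix, compared against Kimura
two-parameter (K2P) distances computed from aligned mitochondrial ND2
sequences, using a one-tailed (negative association) Mantel permutation
test.

**Synthetic fixtures.** Because field photographs are rarely shareable, a
simulator generates masked fish images (elliptical body, class-specific
3-color palettes, stripe bars, Gaussian noise) and landmark configurations
(template scaled to a class-specific body box plus jitter) with known
structure, so the entire pipeline is testable end to end.

## Worked example

Six synthetic classes in three species pairs: each pair shares its color
palette and stripe pattern, and pair members differ only in body height —
so color and stripe information alone cannot separate them, and shape can.

```r
library(finstripe)

make_pair_specs <- function() {
  base <- list(c(150, 90, 40), c(40, 90, 200), c(60, 160, 70))
  specs <- list()
  for (p in 1:3) for (s in 1:2) {
    b <- base[[p]]
    pal <- list(list(rgb = b, prop = 0.55),
                list(rgb = pmin(255, b + 60), prop = 0.30),
                list(rgb = round(b / 2), prop = 0.15))
    specs[[length(specs) + 1]] <- class_spec(
      label = sprintf("sp%d_%s", p, c("short", "tall")[s]),
      palette = pal, stripe_count = 2, stripe_orientation = "vertical",
      body_height_px = c(46, 78)[s],
      landmark_noise_sd = 1.5, color_noise_sd = 8)
  }
  specs
}

ds <- generate_dataset(make_pair_specs(), n_per_class = 12, seed = 1)

cfg48 <- pipeline_config(seed = 1, use_gm = FALSE,
                         cv = cv_config("svm", n_reps = 20, seed = 1))
cfg82 <- pipeline_config(seed = 1, cv = cv_config("svm", n_reps = 20, seed = 1))
run_pipeline(ds$images, ds$landmarks, ds$labels, cfg48)
#> <fin_report> 72 specimens, 6 classes, SVM x 20 reps
#>   features used: 48
#>   CV accuracy: 50.4% (s.d. 15.3)
run_pipeline(ds$images, ds$landmarks, ds$labels, cfg82)
#> <fin_report> 72 specimens, 6 classes, SVM x 20 reps
#>   features used: 82 (incl. 34 shape coordinates)
#>   CV accuracy: 100.0% (s.d. 0.0)
```

With color and stripe features only, the classifier resolves the three
palettes but guesses within each pair (50.4% ≈ the 50% within-pair
ceiling); appending the 34 Procrustes coordinates separates the pairs
completely. On real photographs the boost is smaller but the direction is
the same — body shape carries class information that the color summary
misses.

A command-line interface wrapping the same functions ships in
`inst/scripts/finstripe`:

```sh
Rscript inst/scripts/finstripe simulate --classes 12 --n-per-class 10 \
    --seed 1 --out-dir sim
Rscript inst/scripts/finstripe extract --images sim/images --out features.csv
Rscript inst/scripts/finstripe run --classifier rf --reps 100 --seed 1 \
    --out-dir report
```

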