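---
title: "Color, stripe and shape features for cichlid identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color, stripe and shape features for cichlid identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finstripe)
```

# The problem

Rock-dwelling cichlids of Lake Malawi (mbuna) radiated into hundreds of
species over roughly a million years. Congeneric species — and the two
sexes within a species, which are strongly dichromatic — differ in
coloration, melanic stripe patterns and subtle aspects of body shape.
These differences are real but small: non-expert humans sort such
photographs with well under 50% accuracy. `finstripe` implements a
pipeline that quantifies color, stripe complexity and body shape from
standardized lateral photographs and evaluates how well statistical
classifiers can recover species/sex classes from them, then asks whether
the classes that the classifier confuses are also the classes that are
genetically close.

This vignette explains each stage, its assumptions, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-fixture
tests do and do not demonstrate.

# Background masking

All feature computations operate on a `masked_image`: an 8-bit RGB raster
plus a logical foreground mask. Background pixels are held at a fixed
sentinel color, pure magenta (255, 0, 255) — a color that does not occur
on fish bodies — and the mask is, by construction, exactly the complement
of the sentinel pixels. Every downstream statistic iterates over the mask,
so adding, removing or recoloring background pixels provably cannot change
a feature (this is asserted by tests that re-embed a foreground in a
larger canvas and compare vectors).

Real photograph segmentation is a pluggable contract:
`remove_background()` accepts any function mapping a raster and bounding
box to a foreground mask. The bundled reference segmenter is a
border-seeded color-distance threshold — it estimates the background color
from the image border and marks pixels within a Euclidean RGB distance
`tol` (default 40) of it as background. This is deliberately simple: the
scientific content of the package is the feature set, not the segmenter,
and graph-cut-style algorithms can be plugged in where image material
demands them. Segmentation must preserve the majority of the true
foreground; an empty result is an error, and the operation is idempotent
on its own output.

Lossless PNG fixtures use exact sentinel equality. JPEG compression
perturbs colors, so JPEG loading classifies pixels within an L∞ distance
of 8 intensity units of the sentinel as background; the residual
disagreement concentrates in a thin ring at the body boundary.

An optional per-image channel stretch (`normalize_colors()`) maps each
foreground channel linearly onto [0, 255]. It is off by default and should
stay off for collections: because it is fitted per image, it makes colors
inconsistent across photographs and measurably degrades downstream
classification.

# The 48-element feature vector

In fixed order: 42 palette features, the color ratio, the grayscale
entropy, the normalized edge count and three straight-line counts.

**Palette (42).** Foreground pixels are quantized into k = 7 dominant
colors — the "optimum palette generation" family of image operations —
using k-means in RGB space (Lloyd's algorithm, 3 restarts, fixed seed).
Pixels are canonically sorted by color before clustering, which makes the
result invariant to pixel positions, and the seed makes it deterministic.
When the foreground contains at most 7 distinct colors they are returned
exactly, bypassing the clustering, and unused slots are padded with the
last color at count 0 so that the vector length never varies. Each palette
entry contributes R, G, B and H, S, V, all scaled to [0, 1] so the 42
features share a scale; HSV is derived from the quantized RGB centroid.
Supplying both color models is intentionally redundant in the nonlinear
sense: HSV is a nonlinear transform of RGB, so a linear classifier gains
information from seeing both.

**Color ratio (1).** Pixel count of the most frequent color divided by the
second most frequent (600 brown and 500 blue pixels give 1.2). A
single-color foreground makes the ratio undefined; the extractor records
`NA` rather than aborting the vector, and the pipeline drops the column
when it cannot be used.

**Entropy (1).** Shannon entropy, base 2 with 0·log 0 = 0, of the 256-bin
intensity histogram of the BT.601 grayscale foreground. Bounded by [0, 8]
bits; a proxy for stripe-pattern complexity.

**Edge count (1).** Canny edge detection (Gaussian smoothing σ = 1.4,
Sobel gradients, non-maximum suppression at 45° direction quantization,
hysteresis thresholds 50/150 on raw Sobel magnitude — the OpenCV threshold
convention, in which an intensity step of height d yields a magnitude near
4d). Edge pixels on the foreground are counted and divided by the
foreground pixel count: raw edge totals grow linearly with body size while
area grows quadratically, so the normalization makes differently sized
fish comparable. The gradient magnitude is rounded at the 6th decimal
before suppression so that ties on flat regions resolve identically
regardless of scan order, keeping the edge map exactly equivariant under
90° rotation (a tested property).

**Line counts (3).** Straight segments on the foreground-restricted edge
map, binned at 45° granularity into horizontal (~0°), diagonal (~45°/135°)
and vertical (~90°) counts. The detector is a deterministic scan-line
variant of the probabilistic Hough transform: edge pixels are scanned
along rows, columns and both diagonal families; maximal runs spanning at
least `min_length` pixels (default 15) with internal gaps up to `max_gap`
(default 3) count as one segment each. At 45° granularity the
randomized-voting machinery of the probabilistic Hough adds nothing but
nondeterminism, which the test suite cannot tolerate; the scan-line
formulation detects the same axis-aligned and diagonal structure
deterministically. Both parameters, and the Canny thresholds, are exposed
in `extractor_config()` because line detection on natural objects is
fragile and needs tuning per image scale.

# F-score feature selection

For feature i with classes C, the score is the sum over classes of the
squared deviation of the class mean from the global mean divided by the
sum of the per-class sample variances (n−1 denominator):

$$F(i) = \frac{\sum_{c \in C} (\bar x_{i,c} - \bar x_i)^2}
             {\sum_{c \in C} \mathrm{Var}_c(x_i)}.$$

This is the standard two-class screening score generalized additively to
many classes, consistent with reading the denominator as "the sum of the
variance of each class". The score is invariant under affine transforms of
the feature and under class relabeling (both tested); all-constant classes
give an infinite score with a warning. Features with F ≥ 0.7 are kept by
default — at that threshold a six-feature block scoring (0.42, 0.98, 1.08,
0.93, 0.46, 1.15) drops its first and fifth members. The comparison is ≥
(methods phrasing) rather than > (results phrasing); no practical score
sits exactly on the threshold, so the choice is inert, but it is
documented here. Selection applies to the 48 image features only; the 34
Procrustes coordinates are always retained, because shape variables enter
the analysis as a deliberately added information block rather than as
candidates in the color/stripe screen.

Attribute scaling (`scale_features()`) maps each feature linearly from its
training-set range onto [0, 1] (or [−1, 1]); constant features map to the
lower bound, test values outside the training range are not clipped, and
the map is always fitted on training rows only — fitting it on pooled data
would leak test information into the classifier.

# Landmark morphometrics

Seventeen landmarks per specimen are read from TPS files (`LM=17`, 17
coordinate lines, optional `ID=`/`IMAGE=`/`SCALE=` lines). Raster y grows
downward while anatomical height grows upward, so y is negated at read
time; the aligned y-coordinates then read directly as heights (the y of
the dorsal and ventral apex landmarks track body height, and the y of the
mouth-tip landmark tracks mouth height).

Generalized Procrustes analysis removes the non-shape variation: each
configuration is centered, scaled to unit centroid size, and rotated by
the least-squares orthogonal rotation onto the running consensus, which is
re-estimated as the mean aligned configuration until its Frobenius-norm
change falls below `tol` (default 1e-10, capped at 100 iterations —
convergence is typically reached in a handful). Two choices deserve
comment:

- **Rotation only, no reflection.** The standard geometric-morphometrics
  convention: a mirrored fish is a different shape, not an alignment
  nuisance. The SVD-based rotation constrains the determinant to +1, and a
  test verifies that a mirrored copy retains nonzero Procrustes distance.
- **No tangent-space projection.** The aligned coordinates are used
  directly as classifier inputs, matching the practice of appending raw
  Procrustes coordinates; for the small shape variation typical of
  congeneric fishes the curvature correction is negligible relative to
  classifier noise.

The aligned configurations flatten to an n × 34 matrix
(`ProcCoord_1x … ProcCoord_17y`) and are appended to the 48 image features
by specimen id (mismatched or permuted ids are an error), giving the
82-variable combined table.

# Classification and cross-validation

Two established back-ends are wrapped behind one interface: an RBF-kernel
SVM (`e1071`, LIBSVM) and a random forest (`randomForest`, mtry = 14,
500 trees — values found by model search on the original study's data and
kept as defaults). The SVM kernel and parameters are deliberately
configurable because no single setting suits all feature sets; the package
default is cost = 10 with gamma = 1/p on [0, 1]-scaled features, a
mid-grid value of the usual LIBSVM search that behaves well across the
synthetic fixtures, and an optional `svm_tune` switch runs a small grid
search per training split for users who want the full procedure at ~25×
the cost.

Evaluation uses repeated random-subsampling cross-validation: `n_reps`
(default 100) independent uniform partitions holding out
floor(`test_fraction` · n) rows (default 20%; 594 specimens give 118 test
rows and 11,800 pooled predictions over 100 repetitions). The partition is
deliberately unstratified — matching a plain random 80/20 split — so a
very rare class can occasionally vanish from a training split; such
repetitions are redrawn and counted rather than silently accepted or
crashed. Scaling (and per-repetition selection, off by default since
selection is normally a one-off global step) is fitted on each training
split only.

The pooled predictions form a confusion matrix with predicted classes in
rows and actual classes in columns: entry (p, a) counts how often class a
was predicted as p, column sums give per-class prediction totals,
per-class accuracy is diagonal over column sum, and overall accuracy is
trace over total. Conservation of these identities is tested exactly.

`colors_vs_accuracy()` repeats the CV using only the 6k features of the k
most frequent palette colors, k = 1…7, quantifying how much signal each
additional color contributes; with well-separated class palettes the first
color alone can carry most of the accuracy.

# The genetics link

Classes confused by the classifier are hypothesized to be genetically
close. The confusion matrix is condensed to a symmetric pairwise
misclassification rate, `(c_ij + c_ji) / (N_i + N_j)` — both confusion
directions pooled over both classes' prediction totals. The published
supplementary material does not define its rate formula; this pooled
symmetric form is the package's documented convention, chosen because it
is symmetric by construction, bounded by [0, 1] and reduces to the
intuitive two-class error rate.

Genetic distances use the Kimura two-parameter model,
d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q), with transition proportion P and
transversion proportion Q over pairwise-comparable sites (gap/ambiguity
columns removed per pair). Computation is delegated to
`ape::dist.dna(model = "K80", pairwise.deletion = TRUE)`; saturated pairs
(the log arguments non-positive) are a hard error rather than an `NaN`.
Classes that share a haplotype — e.g. the two sexes of one species typed
on the same accession — get distance 0.

The Mantel test correlates the m(m−1)/2 upper-triangle entries of the two
matrices (Pearson r) and assesses significance by jointly permuting the
rows and columns of the second matrix, 9,999 permutations by default, with
p = (#{r_perm ≤ r_obs} + 1)/(n_perm + 1). The default tail is *negative*
— higher misclassification should pair with *smaller* genetic distance —
which is why the test is implemented in-package: `vegan::mantel` reports
the upper tail only, and is used in the test suite as an independent
cross-check of the statistic instead. The study-scale comparison (the
published r = −0.259 between SVM misclassification and ND2 K2P distance)
requires the supplementary matrices as transcribed CSV inputs; the package
provides the full CSV → Mantel path and validates it on synthetic matrix
pairs with a constructed negative association.

# The synthetic-fixture generator

The simulator emulates the statistical structure the pipeline assumes, at
test-friendly scale:

- **Canvas** 256 × 96 px (the ~2.75:1 aspect of the original ~1100 × 400
  photographs at roughly a quarter scale), body as an axis-aligned ellipse.
- **Palette**: ~3 dominant colors per class with fixed body-coverage
  proportions, realized as bands along the body so that proportions are
  exact in noise-free images (tested to 1%).
- **Stripes**: bars of width body_width/(2k+1) in the least frequent
  palette color, vertical, horizontal or diagonal — wide enough to create
  detectable straight Canny edges for the line features.
- **Landmarks**: a generic 17-point lateral-fish template scaled to the
  class body box (so dorsal/ventral apex y tracks body height) plus
  i.i.d. Gaussian jitter.
- **Noise**: i.i.d. Gaussian intensity noise clipped to [0, 255]; the
  default class set uses σ = 8 intensity units and 1.5 px landmark jitter
  — visible but not class-destroying, about what camera sensor noise and
  digitizing error contribute at this scale.

Every generator is a pure function of (spec, seed); datasets derive
per-specimen seeds deterministically from one root seed. The default
12-class design mirrors a 12-class (9 species, split sexes) study; a
switch produces either fully disjoint class palettes (testing that color
features alone suffice, CV accuracy ≥ 95%) or pairwise-shared palettes
with body-height differences (testing that the 82-variable table beats the
48-feature table by ≥ 5 accuracy points, and that random-forest importance
ranks the body-height-tracking Procrustes y-coordinates at the top).

What the fixtures do **not** model: pose and illumination variation
(controlled away in the field by a fixed camera platform), fin damage,
ontogenetic change, photographic blur, or the continuous color gradients
of real fish skin. Passing the synthetic suites therefore demonstrates
correctness of the computations and the qualitative behavior of the
pipeline — not that any particular accuracy will be achieved on real
photographs.

# Problem sizes and runtime choices

The test and demonstration runs use 6–12 classes at 8–12 specimens per
class, 10–20 CV repetitions, and 256 × 96 px images; these sizes give
stable qualitative results (the Monte-Carlo s.d. of CV accuracy at 10–20
repetitions is a few points) while keeping a full suite run in the
low minutes on one CPU. Study-scale runs (hundreds of specimens, 100
repetitions) use exactly the same code paths; only `n_reps`,
`n_per_class` and the canvas change.

# Known limitations

- The reference segmenter assumes a near-uniform background; cluttered
  backgrounds need a plugged-in graph-cut segmenter.
- The scan-line segment detector reports segment *counts* only, not
  endpoints, and its 45° binning cannot distinguish, say, 30° stripes
  from horizontal ones.
- k-means palettes at k = 7 can split one perceptual color into two
  clusters under heavy noise; palette-prefix experiments
  (`colors_vs_accuracy`) are the honest way to ask how many colors carry
  signal.
- GPA assumes homologous, non-coincident landmarks; missing landmarks are
  not imputed.
- The Mantel test conditions on the supplied genetic matrix; with
  haplotype-sharing classes the zero distances concentrate leverage in a
  few cells, which is inherent to the design, not fixable in the test.
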