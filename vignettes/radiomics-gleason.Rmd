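---
title: "Gleason-grade radiomics with ROI inflation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gleason-grade radiomics with ROI inflation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radgs)
```

## The problem

Gleason grading of prostate cancer — non-significant (3+3) versus
clinically significant (3+4 and above), and 3+4 versus 4+3 and above —
drives the choice between surveillance and radical treatment, but is
established invasively. Multiparametric MRI offers three quantitative
windows on the same tissue: the apparent diffusion coefficient (ADC,
um^2/ms) from diffusion-weighted imaging, the T2 relaxation time (ms) from
multi-echo imaging, and the uptake rate of dynamic contrast enhancement.
`radgs` implements a radiomics pipeline over these maps whose central idea
is *ROI inflation*: radiologist-drawn lesion outlines on MRI are known to
under-segment the histological tumour, so iterated binary dilation of the
drawn ROI recovers peritumoral tissue whose texture carries grade
information.

The cohort this pipeline is designed around is small (50 lesions across 26
surgical patients, with 13 / 29 / 7 / 1 lesions of Gleason 3+3 / 3+4 / 4+3
/ 4+5) and not publicly deposited. The package therefore ships a
synthetic-data module — class-conditional feature tables parameterised by
the cohort's published summary statistics, and image phantoms with a
controllable core/rim texture gradient — so every stage is testable, and
so the inflation effect can be demonstrated end to end on data whose
ground truth is known.

## Signal models and map fitting

Three per-pixel models are fitted (`fit_adc`, `fit_t2`, `fit_emm`,
vectorised over a slice by `fit_map`):

* Diffusion: $S(b) = S_0 e^{-b \cdot ADC}$, with b-values
  0, 50, 100, 150, 990, 1500 s/mm^2 by default. Internally ADC is in
  mm^2/s and reported in um^2/ms (an exact factor of 10^3).
* Relaxometry: $S(TE) = S_0 e^{-TE/T_2}$, nine echoes from 30 to 270 ms in
  30 ms steps by default.
* Enhancement: the percentage signal enhancement
  $PSE(t) = 100\,(S(t) - S_{base})/S_{base}$ of a DCE course sampled every
  8.3 s is fitted with the empirical model
  $PSE(t) = A\,(1 - e^{-\alpha t})\,e^{-\beta t}$, where $A$ (%) is the
  enhancement amplitude, $\alpha$ (1/s) the uptake rate and $\beta$ (1/s)
  the washout rate.

Design choices worth knowing:

* ADC and T2 use *weighted log-linear least squares* (weights $S^2$, which
  de-bias the log transform) rather than nonlinear fitting: the estimator
  is closed-form, deterministic, and exact on noiseless data. Pixels with
  any non-positive sample are flagged invalid instead of being clamped, to
  avoid log-domain bias. ADC is clipped to [0, 10] um^2/ms and T2 to
  (0, 2000] ms; estimates outside those ranges are flagged invalid.
* The PSE baseline is the mean of the first `baseline_frames` frames
  (default 3 — a typical pre-injection window at 8.3 s resolution); the
  time axis is re-zeroed at the last baseline frame. The EMM fit is
  bounded ($A \in [0, 1000]$, $\alpha \in [0, 10]$, $\beta \in [0, 1]$),
  initialised from the curve ($A_0 = \max PSE$,
  $\alpha_0 = \ln 2 / t_{1/2}$, $\beta_0 = 10^{-3}$), and falls back to a
  fixed 3x3x3 multi-start grid, keeping the best-RMSE fit. Bounds and
  starts are robustness choices, not physiological claims.
* The enhancement-rate feature (`ALPHE`) is the fitted rate constant
  $\alpha$ in 1/s. Clinical summaries sometimes quote the rate on a %/s
  scale; the initial slope $A\alpha$ (%/s) is available via
  `emm_initial_slope` for that reading, but the pipeline's default is the
  model's own rate constant.

## ROI inflation

Inflation is iterated binary dilation with a 2x2 square structuring
element (`dilate_roi`). A 2x2 element has no centre pixel; the default
anchors it at its top-left cell, so each turn grows the mask by one pixel
toward increasing row and column. This reproduces the convention of
common numeric platforms for even-sized elements, at the cost of a
one-pixel-per-turn drift of the ROI centroid — with a 2 px erosion margin,
two default turns recover roughly half of the surrounding rim. An optional
`symmetric` mode alternates the anchor between turns so two turns expand
one pixel in every direction; it is off by default to match the
conventional behaviour. Dilation clips at the image boundary and is
monotone and additive (`dilate(m, a+b) = dilate(dilate(m, a), b)` away
from boundaries).

## Texture features

Each lesion yields a canonical 21-feature vector (`extract_features`): the
ROI means of ADC, ALPHE and T2, plus six gray-level co-occurrence features
per map — Energy, Entropy, Contrast, Correlation, Homogeneity and the
inverse difference moment (IDM) — computed per direction (0, 45, 90, 135
degrees at unit distance) and arithmetically averaged over directions.
Choices the numbers depend on:

* Quantization: 32 uniform levels over the per-ROI min-max range
  (configurable). Per-ROI ranging makes texture scale-free; it also means
  features are not comparable across different `levels` settings.
* Both pixels of a pair must lie inside the (possibly dilated) mask;
  texture is strictly ROI-restricted. Directions with no admissible pair
  are excluded from the average.
* GLCMs are accumulated symmetrically and normalised to probabilities;
  entropy uses the natural logarithm; Correlation is defined as 0 for
  degenerate (zero-variance) matrices.

With these normalised definitions Energy, Homogeneity and IDM lie in
(0, 1] and Entropy in $[0, \ln(32^2)]$. Published tables for the
reference cohort print some texture magnitudes far outside these ranges
(e.g. homogeneity of 41, IDM of 316), which is only consistent with
unnormalised co-occurrence counts or a different formula set; this package
standardises on the normalised Haralick forms and makes no attempt to
reproduce those magnitudes. The bundled reference *statistics* are used to
parameterise the feature-table generator, where only their class
separation matters, not their absolute scale.

## Feature selection and univariate statistics

`relieff` implements multi-class ReliefF: features are range-normalised to
[0, 1]; every sample is visited once (no subsampling, hence deterministic);
per visit the k nearest same-class hits and k nearest per-class misses
(Manhattan distance, distance ties broken by lowest sample index) update
the weights, miss contributions weighted by class priors. Weights lie in
[-1, 1]; a constant feature scores exactly 0. The neighbour count k = 10
is a common convention (the selection rule's origin names none); it is
configurable and distinct from the KNN classifier's k = 5.
`select_positive` keeps features with weight > 0, in descending order —
on the bundled reference weight sets this reproduces the known 13-feature
and 8-feature selections for the two binary tasks.

`anova_screen` (one-way ANOVA across the three grade groups, flagging
p < 0.05) and `ttest_summary` (two-tailed Welch t-test with group
means/SDs) mirror the univariate statistics such studies report. The
ANOVA screen is reported but does not gate the binary-task feature sets —
those use ReliefF alone; Welch rather than pooled-variance is the default
because equal variances are not defensible at these group sizes.

## Class balancing and cross-validation

The 13 vs 37 imbalance of the significant-vs-non-significant task is
handled by SMOTE (`smote`): each synthetic minority row is
$x + \delta (x' - x)$ with $x'$ one of the k = 5 nearest minority
neighbours and one $\delta \sim U(0,1)$ per row, generated until class
counts are equal. Balancing happens *inside training folds only*; the
cross-validation driver never lets a test row become a SMOTE parent, a
scaling statistic, or a grid-search datum (the suite asserts all three).

`cross_validate` runs stratified 5-fold cross-validation (the 80/20 regime
appropriate to n = 50; folds are stratified because unstratified splits of
a 13/37 cohort routinely lose the minority class). Features are z-scored
with training-fold statistics. Three classifiers are provided:

* `svm_rbf`: RBF-kernel SVM with an inner 3-fold grid search over
  $C \in 2^{-5..15}$ and $\gamma \in 2^{-15..3}$ (factor-4 steps),
  one-vs-one for the 3-class task. The source procedure states only that
  these hyperparameters were varied; the powers-of-two grid with nested
  selection is this package's concrete, leakage-safe choice.
* `knn`: k = 5, Euclidean, with the deterministic "nearest" tie rule
  (vote ties resolved by the nearest neighbour among tied classes) —
  implemented in-package because off-the-shelf KNN breaks ties randomly.
* `gaussian_nb`: per-class per-feature normal densities with empirical
  priors and a minimum-expected-cost decision (uniform 0/1 costs by
  default; the cost matrix is configurable since the original's values
  are unstated).

Accuracy is the arithmetic mean over folds; per-fold accuracies and the
pooled confusion matrix are retained.

## The synthetic cohort

`gen_feature_table` draws features independently per class from normal
distributions with the reference cohort's printed means/SDs. No printed
covariance exists, so none is imposed — tables are optimistic about
feature redundancy, and classifier accuracies on them test the *pipeline
machinery*, not clinical attainability. In each printed "a/b" statistic
pair the first value is read as the clinically-significant (respectively
Gleason 3+4) class per the source tables' captions; a `swap` flag inverts
that reading since the order is never stated outright.

`gen_phantom_case` builds truth maps with a star-convex lesion (random
low-order harmonic boundary, mean radius 7-11 px on a 120x120, 1.5 mm
grid). The drawn ROI is the true lesion eroded by 2 px, mirroring
under-segmentation. Texture is a Gaussian-copula random field with uniform
marginals: a smooth base field blended with a pixel-scale component whose
variance fraction ("fine fraction": 0.02 / 0.30 / 0.60 / 0.95 by grade)
orders the classes by spatial decorrelation. The uniform-marginal
transform matters: it makes every class's value distribution identical, so
min-max quantization treats classes symmetrically and GLCM entropy
responds to granularity alone — with Gaussian marginals, range and
marginal-shape effects can invert the intended ordering on small ROIs.
Class amplitude (7-22 % of the tissue value) rises with grade; tissue
values (e.g. ADC 1.50 / 1.35 / 1.22 / 1.12 um^2/ms) fall with grade and
carry a per-lesion log-normal spread of CV 0.18 so adjacent grades
overlap, as they do clinically.

The core/rim structure encodes the inflation premise: inside the drawn
ROI the class field is diluted (25 % class texture, 75 % neutral
mid-granularity field, amplitude halved), while the rim between drawn ROI
and true lesion carries the undiluted class field scaled by
`margin_heterogeneity` (default 2). These defaults were fixed once, by
design-phase calibration, to place the pipeline in the regime the method
targets: significant-vs-non-significant accuracy around 0.70 on the drawn
ROIs, rising to about 0.89 after two inflation turns. Signal series are
generated exactly from the three models above plus additive Gaussian noise
(default 1 % of each modality's baseline), so noiseless phantoms invert to
machine precision and noisy ones exercise the fitting error paths.

What the phantoms deliberately do *not* model: anatomy (no prostate
zones, no organ boundary constraining dilation), Rician noise (Gaussian
is the default for analytic tractability), partial-volume and motion
effects, inter-map misregistration, and any quantitative claim about real
lesion texture — the texture model's only obligation is the ordinal
structure above. Passing tests therefore show that the pipeline measures
what it claims on data with that structure; they do not show that the
reference cohort's accuracies are recoverable from real patients.

## Problem sizes and numerical conventions

The test-suite and acceptance computations use the cohort sizes the
method is designed for (50 lesions, 13/29/7/1) for end-to-end runs, 500
lesions per class for distribution-level checks of the table generator,
10-20 master seeds for Monte-Carlo properties, and 120x120 slices for
map-fitting checks; smaller grids (48-64 px) are used where geometry does
not matter. Ties are broken deterministically everywhere (lowest index in
neighbour searches, first-in-grid-order for SVM hyperparameters); all
randomness flows from explicit seeds through a fixed counter scheme
(`derive_seed`), so every generator, fold split, SMOTE draw and study
report is a pure function of its seed. Degenerate inputs follow explicit
conventions rather than erroring where a value is defensible: constant
ROIs quantize to a single level, zero-variance GLCMs have correlation 0,
constant features get ReliefF weight 0, all-constant groups give ANOVA
p = 1 (or 0 if their means separate), and degenerate t-tests report a
missing p-value.

## Known limitations

* The 2x2 structuring element's drift means default inflation is
  anisotropic; use `symmetric = TRUE` for drift-free expansion when
  fidelity to the conventional operator is not required.
* ReliefF is run per dilation level on the full level table (selection is
  not nested inside CV folds); this mirrors the original procedure but
  lets selection see test labels. A `freeze_selection` flag reuses the
  level-0 set across levels; fold-nested selection would be the natural
  next hardening step.
* Whether the 3-class task should be SMOTE-balanced is unstated in the
  source procedure; the package balances all non-majority classes up to
  the majority count when `use_smote = TRUE`.
* Feature-table sampling is independent per feature; real radiomic
  features are strongly correlated.
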