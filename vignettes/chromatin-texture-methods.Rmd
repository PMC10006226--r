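---
title: "Quantifying nuclear chromatin texture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear chromatin texture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtex)
```

## The problem

Mild acute kidney injury (AKI) reorganizes chromatin in proximal tubule
cell (PTC) nuclei in ways that are largely invisible to a human observer
looking at H&E-stained sections: an experienced rater assigning nuclei to
injured/uninjured classes performs barely above chance. Second-order
texture statistics, by contrast, pick up the change reliably. `chromtex`
implements the full quantitative chain: per-nucleus texture features from
masked regions of interest (ROIs), nonparametric group comparison, and
reference classifiers with ROC analysis — together with a synthetic
nucleus generator that lets every stage be exercised and validated without
access to original micrographs.

## Feature definitions

Each nucleus is a `gray_patch`: the grayscale crop of the mask's bounding
box plus the binary mask itself. All statistics are computed from
masked-in pixels only.

### Gray-level co-occurrence features

After quantization to $G$ gray levels, the co-occurrence matrix at
displacement $(\Delta y, \Delta x)$ holds the probabilities $p(i,j)$ of
observing levels $i$ and $j$ at pixel pairs with that offset. Only pairs
with **both** endpoints inside the mask are counted ("clear outside"
semantics — the cleared background must never contaminate nuclear
texture), each pair in both orders (symmetric matrix). Six features are
computed:

* $\mathrm{ASM} = \sum_{i,j} p(i,j)^2$ — angular second moment
  (uniformity; 1 for a single-valued texture),
* $\mathrm{IDM} = \sum_{i,j} \frac{p(i,j)}{1+(i-j)^2}$ — inverse
  difference moment (local homogeneity),
* $\mathrm{CON} = \sum_{i,j} (i-j)^k\, p(i,j)^n$ — contrast, with the
  generalized exponents defaulting to the standard Haralick choice
  $k = 2$, $n = 1$,
* $\mathrm{COR} = \frac{\sum_{i,j} ij\, p(i,j) - \mu_x\mu_y}
  {\sigma_x\sigma_y}$ — gray-level linear dependency, from the marginal
  means and SDs,
* $\mathrm{SA} = \sum_s s\, p_{x+y}(s)$ and
  $\mathrm{SVAR} = \sum_s (s-\mathrm{SA})^2\, p_{x+y}(s)$ — mean and
  dispersion of the gray-level **sum** distribution
  $p_{x+y}(s) = \sum_{i+j=s} p(i,j)$, $s \in [0, 2(G-1)]$.

The classical sum-statistic literature contains inconsistently printed
versions of the SA/SVAR pair (sometimes both labelled as a "variance",
sometimes with the probability weight dropped); `chromtex` implements the
standard definitions above, which match the verbal descriptions — SA as
the *mean* of the sum distribution and SVAR as its dispersion around SA.

Features are computed at displacement $d = 1$ for the four directions 0°,
45°, 90°, 135° and averaged arithmetically, which is the common usage of
Mazda-lineage texture tools and makes the per-ROI value robust to
in-plane rotation. Per-angle values remain available
(`glcm_config(average = FALSE)`).

On a constant (degenerate) ROI both marginal SDs vanish and COR is
undefined; it is reported as `NA` (flagged, not raised), excluded from
group statistics with a logged warning, and imputed by the training-set
median inside the classifiers.

### Quantization

Quantization policy is deliberately configurable because second-order
features are notoriously sensitive to it:

* `minmax` (default, $G = 64$): the ROI's own min..max is rescaled
  linearly to $0..G-1$. Per-ROI scaling makes features invariant to
  illumination and staining intensity; 6-bit dynamics are the customary
  default of texture-analysis software in this field.
* `bitshift`: drops the low bits of the 8-bit value, preserving absolute
  intensity (a mean shift then *does* move SA).
* `sigma3`: clips to the masked mean ± 3 SD before rescaling, robust to
  isolated extreme pixels.

Whether gray levels should be normalized per ROI or per image is a
genuinely open choice in the field; `chromtex` takes per-ROI as the
default and exposes the rest.

### Wavelet subband energies

A single-level 2D Haar analysis runs on non-overlapping 2×2 blocks
$[[a,b],[c,d]]$:
$LL = \tfrac{a+b+c+d}{2}$, $LH = \tfrac{a-b+c-d}{2}$,
$HL = \tfrac{a+b-c-d}{2}$, $HH = \tfrac{a-b-c+d}{2}$.
The first letter names the filter applied along $y$ (rows), the second
along $x$ (columns) — stated explicitly because tools disagree; thus LH
is the horizontal-detail band. The energy of a detail band is
$E = \sum d^2 / n$ over *included* coefficients, giving `EnLH`, `EnHL`,
`EnHH`.

Masked-ROI handling: pixels outside the mask are filled with the rounded
mean of the masked-in pixels before the transform (so the fill is
texture-neutral), odd dimensions are padded by edge replication, and a
coefficient is included iff its 2×2 support contains at least one
masked-in pixel. This fill-plus-overlap rule is an explicit, documented
approximation — legacy tools do not document theirs.

Two deliberate defaults, both configurable:

* Energies are computed on the **raw** 8-bit patch, not the
  GLCM-quantized one; quantization is a co-occurrence-specific step.
* $n$ is the number of included subband coefficients (mean energy per
  coefficient). Using the ROI pixel count instead divides all energies
  by ≈ 4 (`wavelet_config(denominator = "pixels")`).

Haar at level 1 was chosen because only first-level detail energies are
reported in this application area and Haar is the lineage default; the
orthonormal normalization gives an exact Parseval identity
($\sum x^2 = \sum_\text{bands} d^2$ on fully masked patches), which the
test suite exploits as an oracle.

## Group comparison

`summarize_groups()` reports mean ± SD per group (SD with the $n-1$
denominator) and a two-sided Mann–Whitney U test per feature. When both
groups have ≤ 12 observations the null distribution of U is enumerated
exactly — including under ties, via a dynamic-programming count over
subsets of the pooled midranks — otherwise the normal approximation with
tie correction and continuity correction is used; the two agree to well
under 0.02 at the crossover size. No multiple-testing correction is
applied to the headline p-values (mirroring common practice in this
literature), but a Holm-adjusted column is emitted alongside for
transparency. ROIs are treated as independent observations; with ~100
ROIs per animal this is pseudo-replication, acknowledged rather than
corrected, and a per-animal analysis is the natural extension.

## Classification

`train_and_evaluate()` makes a stratified 80/20 split (preserving the
50/50 class balance), standardizes features using training-set statistics
only, and fits three reference models: binomial logistic regression
(`stats::glm`), a radial-kernel SVM (`e1071::svm`, cost 1,
$\gamma = 1/9$), and a random forest of 100 trees
(`randomForest`). Accuracy uses hard class calls; ROC/AUC uses
continuous scores (predicted probabilities, or the SVM decision value).
Kernel, tree count and regularization defaults are stated, fixed and
exposed in `classifier_config()` — they are reference settings, not the
result of a hyperparameter search. A single seeded split is reported;
everything is bit-reproducible from (feature table, seed).

The ROC sweep groups tied scores and integrates by trapezoid, so the AUC
equals the rank statistic $U/(n_1 n_2)$ exactly — an identity the test
suite checks to $10^{-12}$ — and is invariant under monotone transforms
of the scores.

A binary human rater has a single operating point; `evaluate_rater()`
uses the standard two-segment ROC through it, whose area is
$(\text{sensitivity}+\text{specificity})/2$. `rater_from_rates()`
reconstructs the full confusion table from a reported overall accuracy
and true-positive rate under a known class design, which is how published
single-rater operating points can be re-analyzed without raw calls.

## The synthetic nucleus generator

`generate_nucleus()` stands in for undeposited micrographs. It is a
minimal three-ingredient model chosen to move every feature in the
direction observed for injured PTC nuclei, not a biophysical simulation:

1. **Smooth chromatin field** — Gaussian white noise blurred with a
   Gaussian kernel (`smoothness`, default σ = 6 px), standardized, scaled
   by `base_amplitude` (18 intensity units) around `base_mean` (110);
   this is the control-like texture.
2. **Chromatin clumps** — a Poisson number of Gaussian-profile foci
   (radius 4 px) that pull intensity toward a fixed dark "condensed
   chromatin" level (`base_mean − clump_darkening`, darkening 70) through
   a saturating occupancy, so overlapping clumps never stack below that
   level. Saturation matters: it keeps the dark mode *inside* the ROI's
   intensity range, so under per-ROI min-max quantization the clumps add
   in-range probability mass (raising SA and SVAR) instead of stretching
   the range (which would compress the remaining texture into fewer
   levels and push ASM the wrong way).
3. **Pixel noise** — i.i.d. Gaussian noise (`noise_sd`), the
   high-frequency component that drives ASM/IDM down and CON and the
   wavelet energies up.

The AKI-like class differs in all three: stronger pixel noise (SD 7 vs
4), more clumps (rate 6 vs 0.2 per nucleus), and a +12 mean-intensity
shift. The mean shift is visible in raw intensities and matters under
`bitshift` quantization; the default per-ROI min-max scaling deliberately
removes it, which is exactly the illumination-invariance the default is
chosen for. The direction of COR is intentionally unconstrained — its
increase in real injured nuclei is small and its mechanism unclear, so
the generator makes no claim about it. With control noise SD 4, the
control-class detail energies sit near noise-SD² ≈ 16, the magnitude
scale reported for real control nuclei.

Masks are random ellipses (semi-axes 24–38 × 16–28 px in a 96×96 patch,
random orientation, small center jitter); the exterior is cleared to
white (255), mimicking ROIs isolated from a bright H&E background.
Everything is reproducible from (config, seed), and
`synthetic_null_config()` equalizes the classes for null-calibration
checks (classifier AUC ≈ 0.5).

What the generator does **not** emulate: H&E color and stain variation
(it is grayscale by construction), nucleoli and other organized
substructure, spatially correlated camera noise, optical blur,
segmentation error in the masks, and between-animal variability (the
animal labels cycle round-robin and carry no random effect). Passing
validation on synthetic data therefore demonstrates that the *pipeline*
measures what it claims to measure — not that real AKI nuclei will
separate with any particular effect size.

## Numerical choices and degenerate inputs

* Co-occurrence matrices must sum to 1 within $10^{-12}$; the vectorized
  accumulator is tested against a brute-force pair enumerator at that
  tolerance.
* An offset admitting zero valid pairs raises an error naming the
  offset; a constant ROI yields COR `NA` (see above) but valid values
  for the other eight features.
* Quantization maps are monotone non-decreasing by construction; a
  constant ROI maps to level 0 under `minmax` and `sigma3`.
* ROIs with fewer than 8 masked-in pixels are rejected at ingest;
  synthetic masks are regenerated (bounded retries) below 64 px of area.
* Ties in ROC scores are grouped into single sweep steps; ties in the
  Mann–Whitney test use midranks with the tie-corrected variance or the
  exact DP enumeration.

## Validation problem sizes

The test suite validates the oracle identities on 50 masked 16×16
patches (co-occurrence brute force), 100 random patches (Parseval), a
noise-response study of 200 replicate ROIs at four noise levels, a
direction-recovery study of 100 nuclei per class, and classifier checks
on the full 700 + 700 design plus its null variant. These sizes give the
Monte-Carlo checks comfortable power while keeping a full test run in
well under a minute of compute for the texture primitives and a few tens
of seconds for the study-scale checks.

## Known limitations

* Only the six co-occurrence features above are implemented; other
  Haralick statistics (entropy, difference variance, …) are out of
  scope.
* Only level-1 Haar detail energies are computed; no multi-scale
  decomposition, no LL energy, no other wavelet families.
* BMP input is not supported (no installed reader); use PNG or TIFF.
* No stain normalization, nucleus segmentation or color deconvolution:
  ROIs and masks are taken as given.
* Classifier evaluation pools ROIs; per-animal cross-validation is not
  implemented.
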