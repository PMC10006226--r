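# chromtex

Nuclear chromatin texture analysis for histology: gray-level
co-occurrence matrix (GLCM) features and Haar wavelet subband energies
from masked nuclear regions of interest (ROIs), with nonparametric group
comparison and reference classifiers.

## What problem this solves

Mild acute kidney injury (AKI) subtly redistributes chromatin in proximal
tubule cell nuclei. The change is essentially invisible to a human
observer in H&E sections — a trained rater classifying nuclei as
injured/uninjured performs near chance — but it is measurable with
second-order texture statistics. `chromtex` is for image-analysis and
nephropathology researchers who want that measurement chain as tested,
scriptable R code rather than a GUI tool: per-nucleus feature extraction,
AKI-vs-control statistics, and machine-learning classification with ROC
analysis.

Nine features are computed per nucleus from its masked gray-level patch:

* **GLCM** (on the G = 64-level quantized patch, distance 1, four
  directions averaged): angular second moment
  ASM = Σ p(i,j)², inverse difference moment
  IDM = Σ p(i,j)/(1+(i−j)²), contrast CON = Σ (i−j)ᵏ p(i,j)ⁿ (k = 2,
  n = 1), correlation COR = (Σ ij·p(i,j) − μxμy)/(σxσy), and the sum
  average SA = Σ s·p_{x+y}(s) and sum variance
  SVAR = Σ (s−SA)²·p_{x+y}(s) of the gray-level sum distribution.
* **Wavelet** (level-1 orthonormal Haar on the raw 8-bit patch): detail
  subband energies EnLH, EnHL, EnHH with E = Σ d²/n over coefficients
  whose support touches the mask.

Injury manifests as ASM and IDM decreasing while CON, SA, SVAR and all
three energies increase. Because the original micrographs of such studies
are typically not deposited, the package ships a seeded two-class
synthetic nucleus generator (smooth chromatin field + dark chromatin
clumps + pixel noise) that reproduces that signature and makes every
stage of the pipeline testable end to end. See the methods vignette
(`vignettes/chromatin-texture-methods.Rmd`) for definitions, conventions
and design rationale.

## Worked example

Simulate a 100 + 100 nucleus study, extract features, compare groups and
train the three reference classifiers:

```r
library(chromtex)

cfg  <- synthetic_config(n_per_class = 100)   # defaults define the study
man  <- generate_dataset(cfg, "demo_data")    # PNGs + manifest.csv
feats <- extract_features(man)                # 200 x 9 feature table
summarize_groups(feats)
```

```
 feature     mean+/-sd (ctrl)     mean+/-sd (AKI)    U            p
     ASM 0.00217 +/- 0.000651 0.00176 +/- 0.00032 7038 6.411044e-07
     IDM     0.218 +/- 0.0338    0.193 +/- 0.0125 7391 5.191298e-09
     CON        27.9 +/- 9.51         34 +/- 5.33 2730 2.934991e-08
     COR     0.888 +/- 0.0402    0.874 +/- 0.0345 6477 3.089666e-04
      SA          67 +/- 8.25       69.8 +/- 6.74 3808 3.599307e-03
    SVAR          481 +/- 107         530 +/- 111 3776 2.794470e-03
    EnLH        23.3 +/- 3.24         73 +/- 10.9    0 2.562144e-34
    EnHL        23.9 +/- 4.41       72.9 +/- 11.9    0 2.562144e-34
    EnHH           18 +/- 1.8       52.4 +/- 4.47    0 2.562144e-34
```

The injured class shows the expected signature: uniformity (ASM) and
local homogeneity (IDM) fall, while contrast, the sum statistics and the
wavelet detail energies rise, each with a two-sided Mann–Whitney p-value
(Holm-adjusted values are in the returned table). On the held-out 20%:

```r
train_and_evaluate(feats, seed = 1)
#> Held-out classifier performance
#> logistic_regression  accuracy 1.000  AUC 1.000  (train 160 / test 40)
#> svm                  accuracy 1.000  AUC 1.000  (train 160 / test 40)
#> random_forest        accuracy 1.000  AUC 1.000  (train 160 / test 40)
```

(The synthetic classes are deliberately well separated; on real
micrographs these models land far below 1.) A published single-rater
operating point can be re-analyzed from its printed rates — here, 55.1%
accuracy with a 10.7% true-positive rate on a 700/700 design:

```r
rater_from_rates(accuracy = 0.551, tp_rate = 0.107, n_pos = 700, n_neg = 700)
#> Binary rater evaluation
#>   TP 75  FP 4  TN 696  FN 625
#>   accuracy 0.551  sensitivity 0.107  specificity 0.994
#>   single-point AUC 0.551
```

i.e. an AUC of 0.55 — no better than guessing, which is precisely why
the quantitative features are needed.

The whole chain also runs as one call (`run_pipeline(run_config(), "out")`)
or from the shell via `exec/chromtex` with subcommands `run`, `simulate`,
`features`, `compare`, `classify` and `rate-eval`; real micrographs enter
by pointing a manifest CSV (`roi_id,image_path,mask_path,group,animal_id`)
at PNG/TIFF images and masks.

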