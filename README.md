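# tonguemetrics

Quantitative tongue-image analysis for case-control studies, in the style of
computerized traditional Chinese tongue diagnosis ("automatic tongue diagnosis
systems"). The package is aimed at researchers who want to reproduce or
prototype that kind of study without access to a clinical capture device: it
couples a feature-extraction layer for tongue photographs with the standard
case-control statistical toolkit, and ships synthetic-data generators so the
whole pipeline is testable end to end.

## What it computes

**Image features.** A tongue photograph is split into two regions — the tongue
*body* (the tissue surface) and the tongue *coating* (the deposit layer) — and
each region is summarised by:

- **12 chromatic indexes**: mean R, G, B; hue H, brightness I and saturation S
  from the geometric HSI transform

  I = (R + G + B) / 3,
  S = 1 − 3·min(R, G, B) / (R + G + B),
  H = arccos{ ½[(R−G) + (R−B)] / √[(R−G)² + (R−B)(G−B)] },
  with H := 360° − H when B > G;

  CIE L\*a\*b\* (sRGB, D65; L\* reported on a 0–255 scale); and full-range
  BT.601 YCbCr.

- **4 gray-difference texture statistics** from the normalised histogram
  h_g(i) of absolute luma differences at a small pixel offset (Δi, Δj):

  MEAN = (1/m) Σ i·h_g(i),  CON = Σ i²·h_g(i),
  ASM = Σ h_g(i)²,  ENT = −Σ h_g(i)·log₂ h_g(i).

**Statistics.** Uncorrected Pearson χ² for 2×2 tables (Yates optional),
Mann–Whitney U (exact by enumeration for small samples, tie-corrected normal
approximation otherwise), pooled two-tailed t test (raw data or summary
statistics), univariate logistic regression in closed form for 2×2 tables
(OR = ad/bc with Woolf standard errors and Wald 95% CIs), multivariate
logistic regression by Newton–Raphson/IRLS, Spearman rank correlation with
midranks, and ROC/AUC for binary and continuous markers with Hanley–McNeil
confidence intervals.

**Synthetic data.** `generate_tongue_image()` renders elliptical tongues with
known body/coating masks, controllable coating fraction, sinusoidal texture
and gray noise; `generate_cohort()` simulates case-control cohorts with
prescribed categorical marginals, range-truncated log-normal blood markers
anchored at printed medians, and Gaussian-copula rank correlations between a
marker and an image feature.

## Worked example

```r
library(tonguemetrics)

# a synthetic tongue with known ground truth, then the full feature record
gen <- generate_tongue_image(image_spec(seed = 7))
feats <- extract_features(gen$image, gen$masks)
feats[, c("region", "R", "G", "B", "H", "I", "S", "CON", "ASM", "ENT", "MEAN")]
#>    region     R      G      B     H     I       S   CON     ASM   ENT    MEAN
#> 1    body 179.9  89.89  94.89 357.2 121.6 0.26052 59.34 0.07027 4.042 0.02408
#> 2 coating 205.1 195.11 185.11  30.0 195.1 0.05125 58.37 0.07109 4.028 0.02386
```

The body region reads as a saturated light red (H near 360°, S = 0.26) and the
coating as a bright, nearly achromatic pale tone (I = 195, S = 0.05) — exactly
the contrast the body/coating split keys on. MEAN ≈ 0.02 reflects the 1/m
scaling of the histogram mean.

Case-control statistics from a 2×2 table (38/40 cases vs 6/40 controls with a
greasy coating):

```r
greasy <- matrix(c(38, 6, 2, 34), 2)  # rows: exposed yes/no; cols: case/control
chi_square_2x2(greasy)
#> Pearson chi-square: statistic = 51.7172, p = 6.41e-13
logistic_univariate_2x2(greasy)
#>             coef        se       OR   ci_low  ci_high            p
#> exposure 4.67904 0.8499378 107.6667 20.35227 569.5733 3.688415e-08
roc_auc_binary(38, 40, 6, 40)
#> AUC = 0.9000, 95% CI (0.8295, 0.9705), p vs 0.5 = 7.348e-10  [40 cases, 40 controls]
```

So a greasy coating multiplies the odds of being a case by ~108 (Wald 95% CI
20.4–569.6) and, used alone as a classifier, reaches AUC 0.90.

An end-to-end run over a simulated study (cohort CSV + per-subject images +
masks + YAML config, then all five report tables):

```r
cfg <- simulate_study("demo", n_glm = 40, n_control = 40, seed = 1)
report <- run_pipeline(cfg)   # writes report.json, table2..table5.csv, roc.csv
```

The same is available from a shell via the thin CLI in `exec/`:
`tonguemetrics simulate|extract|analyze`.

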