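---
title: "Methods: chromatic and texture profiling of tongue images with case-control statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatic and texture profiling of tongue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguemetrics)
```

## The measurement model

Computerized tongue diagnosis treats a tongue photograph as two regions — the
tongue *body* (tissue) and the tongue *coating* (the deposit layer on it) —
and summarises each region by a vector of colour and texture indexes that are
then carried into ordinary case-control statistics. tonguemetrics implements
that measurement chain and the statistics behind the resulting report tables.

The chain is: load an 8-bit sRGB raster → isolate the tongue → partition it
into body and coating → compute, per region, twelve chromatic indexes and four
gray-difference texture statistics → compare groups, regress case status on
categorical tongue features, and correlate image features with blood markers.

### Chromatic indexes

Per region we report R, G, B (mean channel intensities, 0–255) and three
derived colour spaces:

* **HSI.** I = (R+G+B)/3; S = 1 − 3·min(R,G,B)/(R+G+B); H =
  arccos{½[(R−G)+(R−B)] / √[(R−G)² + (R−B)(G−B)]}, reflected to 360° − H when
  B > G. H is in degrees in [0, 360); achromatic pixels (R = G = B, including
  black) return H = 0, S = 0 by convention, since the H denominator vanishes
  and S is otherwise 0/0 at black.
* **CIE L\*a\*b\*.** Standard sRGB linearisation → XYZ (D65, 2° observer) →
  CIELAB. We report L\* on a 0–255 scale (× 255/100): instruments in this
  field report lightness alongside 8-bit channels, and observed tongue L\*
  values above 130 are only consistent with that scaling. a\* and b\* are left
  unshifted and sign-carrying (pale coatings genuinely produce negative b\*).
  Both scalings are options (`l_scale`).
* **YCbCr.** Full-range BT.601 ("JPEG") coefficients, Cb/Cr centered at 128
  and clipped to [0, 255]. Studio-swing variants exist in instruments, but
  full range is the common image-processing default; the choice is isolated
  in `rgb_to_ycbcr()`.

**Aggregate-then-convert.** `profile_region()` converts the region's *mean
RGB triple* once, rather than averaging per-pixel conversions: an arithmetic
mean of hue is ill-defined under wraparound (358° and 2° average to 180°), and
group-comparison tables consume one value per region. A `mode = "per-pixel"`
switch provides the alternative for sensitivity analysis; the two modes
coincide exactly on constant regions, which is where the golden tests pin
values.

### Gray-difference texture statistics

For gray image f (BT.601 luma rounded half-to-even to the m-level grid,
m = 256 by default) and a small offset (Δi, Δj), the difference image is
g(i, j) = f(i, j) − f(i+Δi, j+Δj) over all pixel pairs with both ends inside
the region mask. hg is the normalised histogram of |g| over bins 0 … m−1, and

* MEAN = (1/m) Σ i·hg(i) — the histogram mean scaled by 1/m (hence the
  characteristic 0.02–0.03 magnitude on 8-bit tongue images),
* CON = Σ i²·hg(i) — contrast, in squared gray levels,
* ASM = Σ hg(i)² — angular second moment (energy), in (0, 1],
* ENT = −Σ hg(i)·log₂ hg(i) — entropy in bits, with 0·log 0 := 0.

Published transcriptions of these four formulas are frequently garbled
(missing exponents, a log of the bin index rather than of the probability).
We implement the standard gray-level-difference-statistics forms above; they
are the only readings whose ranges are coherent — ASM must lie in (0, 1] and
equal 1 exactly when ENT = 0; ENT must be finite when bin 0 is occupied — and
whose magnitudes match the values such instruments report (ASM ≈ 0.04–0.23,
ENT ≈ 1.2, MEAN ≈ 0.02–0.03).

Differences are binned by absolute value: signed differences would double the
support (halving ASM) and |g| is the standard convention. The default offset
is Δ = (1, 1); an offset matrix pools the pairs of several offsets (e.g. the
four standard ones) into one histogram. The entropy log base defaults to 2
and is configurable. A brute-force double-loop oracle (`texture_oracle()`)
recomputes everything without shared code; the test suite holds the two paths
to 1e-12 agreement on random masked images.

One subtlety: the luma grid makes the statistics shift-invariant for *even*
integer gray shifts exactly; odd shifts can flip the parity of exact .5 lumas
under round-half-to-even. The shift-invariance property test therefore uses
gray images, where luma is integral.

### Segmentation and the body/coating split

The capture style this emulates photographs a well-lit tongue against a dark
background, so `segment_tongue()` uses thresholding — a pixel is a candidate
if it is *saturated and red* (body tissue) or simply *bright* (pale coating) —
followed by morphological closing (disc of radius 3) and the largest
connected component. `split_body_coating()` classifies a tongue pixel as
coating when S < 0.15 and I > 140 (coatings are whiter and paler than the
body); every tongue pixel lands in exactly one of body/coating, an invariant
`region_masks()` enforces on construction.

These thresholds are fixture-calibrated conveniences, not contributions: all
quantitative feature tests also run with ground-truth masks supplied
directly, so segmentation quality never gates the math. Real clinical
segmentation (shadowed backgrounds, lips, teeth) would need more than
thresholding; that is out of scope.

## The statistics module

All test statistics are authored from their defining formulas (base R
supplies only the distribution tails):

* **Pearson χ²** for 2×2 tables, *uncorrected* by default — the variant that
  reproduces printed case-control tongue-feature p-values — with Yates'
  correction behind a flag. Zero margins raise a "degenerate margin" error.
* **Univariate logistic regression on a 2×2 table** in closed form:
  OR = ad/bc, SE(log OR) = √(1/a+1/b+1/c+1/d), Wald CI with z = 1.959964
  (the extra digits matter at the precision printed CIs carry). A zero cell
  is an error by default (the MLE does not exist); Haldane–Anscombe +0.5 is
  available by flag.
* **Multivariate logistic regression** by Newton–Raphson/IRLS, converged when
  max |score| < 1e-8, capped at 50 iterations; Wald SEs from the inverse
  observed information. Perfect separation is detected by coefficient
  divergence (|β| > 30) and flagged as non-converged rather than raised.
  On a single binary predictor the IRLS fit equals the closed form to 1e-8,
  a dual-route check in the suite.
* **Mann–Whitney U** from summed midranks. With n₁+n₂ ≤ 12 and no ties the
  two-sided p is exact: P(|U − n₁n₂/2| ≥ |u − n₁n₂/2|) under the null pmf
  computed by the counting recursion N(u; m, n) = N(u−n; m−1, n) +
  N(u; m, n−1). Otherwise a normal approximation with midrank tie correction
  and 0.5 continuity correction. The exact path is verified against full
  enumeration over rank assignments.
* **Pooled t test** (df = n₁+n₂−2), callable from summary statistics, since
  published tables often carry only mean ± SD per group.
* **Spearman** as Pearson on midranks; p from the t approximation on n−2 df.
* **ROC/AUC**: rank-based AUC with midrank ties; for a binary marker this
  reduces to (sensitivity + specificity)/2. The 95% CI uses the
  Hanley–McNeil SE at the estimated AUC; the p-value tests AUC = 0.5 with
  the Hanley–McNeil SE evaluated *under the null* — the convention that
  matches how such studies report ROC significance.

No multiple-testing correction is applied anywhere: the pipeline mirrors the
single-α reporting style of the studies it reproduces, and this is a
deliberate, documented limitation (the table-5-style Spearman grid screens
many pairs at unadjusted p < 0.05).

The three-level ordinal features (tongue shape, body colour, coating colour)
are compared with the rank-sum test on documented ordinal scores
(small/thin < moderate < fat; light red < red < dark red; none < white <
yellow). Published ordinal p-values are not reproducible without knowing the
original coding, so they are not golden-tested.

## The synthetic-data generators

The generators define the study conditions the tests run under; their
defaults are fixed once and are not tuning knobs.

**Images.** An axis-aligned ellipse (semi-axes 0.42·width, 0.45·height) on a
dark background; the coating is the anterior-shifted concentric patch of
exactly round(coating_fraction · n_tongue) tongue pixels (nearest elliptical
distance, deterministic tie-break), so the ground-truth fraction is exact by
construction. Controllable texture comes from a sinusoid (amplitude 8 gray
levels, period 24 px by default); noise is one N(0, noise_sd) gray-level draw
per pixel added to all channels — "gray" noise, which leaves saturation
nearly unchanged and is what the luma-based texture statistics measure.
Defaults depict a light-red body (180, 90, 95) with a whitish coating
(205, 195, 185) over 35% of the surface and noise_sd = 5. No claim of
photorealism: geometry, optics and illumination of real capture devices are
not modelled, so passing tests certify the *math*, not clinical validity.

**Cohorts.** Default categorical marginals are the observed 40 + 40
case/control proportions of the granulomatous-lobular-mastitis tongue study
this design follows (greasy coating 95% vs 15%, thick 85% vs 12.5%, all case
tongues light red, …). Blood markers are log-normal — medians with strongly
right-skewed printed ranges identify a right-skewed positive family — with
sdlog set so the printed min–max range spans a ~98% envelope, samples
confined to the printed range by inverse-CDF truncation (no boundary point
mass), and meanlog solved numerically so the *truncated* distribution's
median equals the printed median (plain log(median) drifts visibly when the
median sits asymmetrically in the log-range, as for IL-2). Rank correlations
between a marker and a named feature column are induced per group through a
Gaussian copula with Pearson parameter 2·sin(πρ_S/6), which targets the
population Spearman ρ_S directly; the truncated-quantile transform is
monotone, so ranks are preserved.

Only marginals are controlled: the generator does not model the joint
distribution across features (greasy × thick, say), so multivariate
odds-ratio magnitudes from real data cannot be matched by construction —
the multivariate fit is tested for correctness (against `glm`, recovery of
known β), not against printed multivariate ORs.

## Problem sizes and numerical choices in the test suite

The suite pins printed-value reproductions exactly where they are functions
of printed counts (χ² p-values, ORs and Wald CI bounds, binary AUCs, the
summary-statistic t test). Stochastic checks use fixed seeds and sizes chosen
to keep the full suite under a minute: 100 random 16×16 images for the
texture oracle, all sample-size pairs with n₁+n₂ ≤ 10 for exact Mann–Whitney
vs enumeration, n = 5000 for logistic recovery of β = (−1, 1.5) within ±0.1,
500 cohorts of 40 cases for the copula Spearman target −0.32 within ±0.04,
and 10,000 null 2×2 tables (40 per group, exposure probability 0.5) for
type-I calibration within [0.03, 0.07] at α = 0.05. `scripts/acceptance.R`
recomputes the same quantities from scratch at run time.

## Known limitations

* Segmentation is a threshold heuristic calibrated to the synthetic fixtures;
  it is bypassable (and bypassed in all golden tests) via ground-truth masks.
* JPEG input is not supported (no lossless guarantee and no reader among the
  package's dependencies); PNG is the primary format, TIFF optional.
* The HSI hue mean in `mode = "per-pixel"` is a plain arithmetic mean and is
  unreliable for regions straddling the 0°/360° boundary; the default
  aggregate-then-convert mode avoids this.
* Printed odds ratios that are inconsistent with any 2×2 reading of their own
  count tables (a known hazard of published tables) are flagged by the
  univariate/closed-form route rather than chased.
* No colour calibration of capture devices, no clinical interpretation.
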