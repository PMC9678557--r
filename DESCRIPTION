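Package: tonguemetrics
Title: Chromatic and Texture Profiling of Tongue Images with Case-Control Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tongue-image analysis for case-control studies in the
    style of computerized traditional Chinese tongue diagnosis. Extracts twelve
    chromatic indexes (RGB means; hue, brightness, saturation; CIE L*a*b*;
    YCbCr) and four gray-difference texture statistics (MEAN, CON, ASM, ENT)
    from the tongue body and tongue coating regions of 8-bit RGB photographs,
    and analyses per-subject cohort tables with Pearson chi-square tests,
    Mann-Whitney U tests, two-tailed t tests, univariate and multivariate
    logistic regression with Wald odds-ratio confidence intervals, Spearman
    rank correlation, and binary-marker ROC/AUC. Includes a synthetic-data
    module that renders elliptical tongue images with known body/coating masks
    and simulates cohorts with prescribed categorical marginals, log-normal
    blood markers, and copula-induced rank correlations, so the full pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
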