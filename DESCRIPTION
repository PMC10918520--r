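Package: wutdiag
Title: Diagnostic Accuracy of the Weight, Urine Colour and Thirst (WUT)
    Hydration Venn Diagram
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the weight, urine colour and thirst (WUT) Venn-diagram
    hydration classification and its diagnostic-accuracy evaluation against
    urinary and blood reference standards (urine specific gravity, urine
    osmolality, plasma osmolality). Provides a synthetic-cohort generator that
    reproduces a repeated-measures spot-sample study design (24 participants,
    free-living and euhydrated conditions, 3 consecutive days, morning and
    afternoon timepoints) with a latent dehydration state driving correlated
    hydration markers and stratified plasma-sample missingness; per-visit WUT
    scoring against configurable thresholds; binary reference calls; 2x2
    contingency tables, sensitivity, specificity, predictive values, ROC
    operating points and cut-off determination (Youden or closest-to-(0,1));
    and study-shaped summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
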