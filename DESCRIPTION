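Package: limbperf
Title: Noninvasive Perfusion Imaging Analysis of Extended Limb Ischemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying tissue oxygenation and perfusion of an
    ischemic limb from noninvasive imaging time series. Extracts
    region-of-interest profiles from 3CCD color (red-minus-blue channel
    surrogate for oxygenation) and long-wave infrared (thermographic
    perfusion) frame sequences, reduces them to reperfusion and
    post-occlusive reactive hyperemia (PORH) slope features, normalizes
    blood chemistry to serum urea, encodes locomotion and pathology scores,
    and predicts return to normal locomotion with a from-scratch partial
    least squares discriminant analysis (PLSDA) classifier evaluated by
    random-subset cross-validation and ROC analysis. Includes a synthetic
    porcine-cohort generator with ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
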