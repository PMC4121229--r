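Package: apoutliers
Title: Arithmetic-Progression-Sum Outlier Detection for Linear Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric detection of significant and nonsignificant outliers
    in linear (arithmetic-progression-like) series using min-max-sum (MMS)
    ratio scores and their enhanced form (EMMS) on a constant-value transform.
    Removed or initially missing values are handled without imputation, either
    by angular-shift recalculation relative to a reference element or by the
    missing-value-invariant constant transform. Includes the two-phase
    iterative detection pipeline with Bad-Detection termination, a synthetic
    linear-series contamination generator, a validation harness, CSV/TSV
    input-output, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
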