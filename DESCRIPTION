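Package: carbquality
Title: Predicting Added and Free Sugars and Carbohydrate Quality of Packaged Foods
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the added-sugar and free-sugar content of packaged foods
    and beverages from on-pack information (the ingredient list and the
    nutrition facts panel), using a gated two-stage model: three tree-based
    binary classifiers decide whether added sugars are present and, if so,
    stacked tree-ensemble regressors predict the amount. Free-sugar estimates
    (declared, predicted, or total-sugar overrides for intrinsically sugary
    categories) feed a carbohydrate-quality score, the 10:1|1:2 ratio: at
    least 1 g of dietary fiber per 10 g of carbohydrate and less than 2 g of
    free sugars per 1 g of fiber. Includes surveillance-style aggregation by
    category, country and launch year with pooled two-proportion z-tests and
    cumulative trend series, a curated regular-expression lexicon for tagging
    sugar-related ingredients, and a synthetic label generator with known
    ground truth for validating every step without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
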