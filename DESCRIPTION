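Package: shadetol
Title: Shade-Tolerance Evaluation of Soybean Germplasm in Intercrop Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate shade tolerance across large soybean germplasm
    panels grown under maize-soybean intercrop shade versus monoculture
    control in split-plot multi-environment trials. Computes per-trait
    tolerance indices and a four-category tolerance classification,
    split-plot and two-way analyses of variance with correct error strata,
    effect sizes and percent changes, control-versus-shade paired
    correlations, path-coefficient analysis of seed yield, principal
    component analysis, quartile-transition identification of elite-stable
    and shade-adaptive genotypes, k-means dissection of the tolerance space,
    and random-forest trait-importance regression. Includes a calibrated
    synthetic split-plot trial generator for validation and power studies,
    and an end-to-end pipeline that writes tables, a machine-readable
    summary, and a Markdown report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
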