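Package: malnut
Title: Geo-Linked Analysis of Child Undernutrition and District-Level
    Program Impact
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating district-level nutrition programs with
    two-wave child anthropometry surveys. Provides a synthetic survey and
    landscape generator, nearest-neighbour linkage of survey points to
    gridded biophysical attributes, undernutrition classification from
    HAZ/WAZ/WHZ Z-scores (stunting, underweight, wasting, composite
    failure, excess prevalence), bivariate screening of candidate
    determinants, backwards p-value model selection with subsampling
    stability selection and model averaging, and a stratified
    quasi-experimental difference-of-changes impact analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
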