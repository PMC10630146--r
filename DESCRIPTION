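Package: plantserve
Title: Plant and Animal Food-Group Servings for Food Composition Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Expands an AUSNUT-style food composition database so that every
    whole food, multi-ingredient product and mixed dish carries quantitative
    plant and animal food-group servings per 100 g. Implements a 23-group
    plant/animal classification schema with mass-, energy- (600 kJ) and
    sodium-based (120 mg Na per 100 g) serving rules, a recipe-disaggregation
    engine using ingredient weights and weight-change (yield) factors, a
    label-based estimator for products without recipes, proxy-product
    fallbacks, and a classification workflow that routes every food through
    these methods. Includes appliers for dietary-intake records,
    population-level summary tables stratified by major food group and
    core/discretionary status, and a seeded synthetic-fixture generator with
    analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
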