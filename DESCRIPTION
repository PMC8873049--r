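Package: psdmap
Title: Mapping Plant Species Diversity by Ensemble Learning and
    High-Accuracy Surface Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping plant species diversity over a raster grid
    from quadrat surveys and remote-sensing covariates. Computes richness,
    Shannon and ecological diversity indices from species-cover records,
    builds vegetation-index and terrain covariate stacks, fits regularized
    linear and tree-ensemble regressions, and fuses their prediction
    surfaces with plot observations through high-accuracy surface modeling
    (HASM), an equality-constrained sparse least-squares solver built on
    the Gauss equations of surface theory. Includes a repeated-holdout
    evaluation harness and a synthetic landscape/survey generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    randomForest,
    stats,
    utils,
    xgboost
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
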