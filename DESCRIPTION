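Package: morphoscore
Title: Regression-Based Phenotype Scoring of 3D Facial Landmark Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric-morphometric pipeline for quantifying a dysmorphic facial
    phenotype from dense homologous 3D landmark configurations. Provides ordinary
    and generalized Procrustes superimposition with unit-size scaling, bilateral
    symmetrization, shape-space principal component analysis with Horn-style
    parallel analysis for component retention, a regression-derived phenotype
    axis (cubic age, sex and group effects) with normalized projection scores
    and per-vertex heatmap fields, paired Hotelling T2 tests of multivariate
    shape change, and longitudinal linear mixed models of score change under
    treatment. Includes a synthetic bilateral landmark cohort generator with
    known group, growth, sex, individual and treatment effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
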