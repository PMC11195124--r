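Package: visig
Title: Vascular Invasion Gene-Expression Signature Analysis for Stage I Lung Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation and validation of a vascular-invasion (VI) gene-expression
    signature for stage I lung adenocarcinoma. Provides negative-binomial GLM
    likelihood-ratio differential expression over a three-level tumor grade factor,
    Ward clustering of the significant genes into directional co-expression clusters,
    bulk mean z-score and spot-level binned-control module scoring, spatially
    weighted local correlation of score maps, mixed-model region association with
    seeded downsampling, distance binning of spots around invaded foci, a
    cluster-proportional 48-gene nested cross-validation ridge-logit VI predictor
    with bootstrap AUROC, multi-region intra-tumor heterogeneity resampling
    statistics, and Cox proportional-hazards / Kaplan-Meier survival association.
    A synthetic-data module generates negative-binomial bulk cohorts with planted
    gene modules, Visium-like spot grids with painted pathology regions, multi-region
    tumors with shared latent scores, and proportional-hazards survival times, so the
    whole pipeline is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    edgeR,
    lme4,
    lmerTest,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
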