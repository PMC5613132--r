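Package: lateralize
Title: Language Lateralization Analysis from Voxelwise Statistical Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing typical and atypical language
    lateralization from volumetric statistical (Z) maps: adaptive-threshold
    laterality indices in paired left/right regions of interest,
    hemispheric extent (diffuseness) statistics, threshold-free
    classification of subjects via spatial-correlation similarity graphs
    and modularity community detection, peak-of-activity localization,
    mirror/conjunction map algebra, Welch and Pearson inferential
    primitives, and a seed-based resting-state connectivity model with
    hemispheric global signals as predictors of interest.  A synthetic-data
    module generates cohorts of activation maps and resting-state runs
    with planted ground truth (laterality, extent-bilaterality coupling,
    group-distinct peak locations, hemispheric global-signal asymmetry)
    for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
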