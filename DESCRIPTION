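Package: thalamoflow
Title: Low-Dimensional Task Hubs and Activity-Flow Mapping of the
    Thalamocortical System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how multi-task evoked fMRI
    activity in a source region (the thalamus) is organized and how it
    predicts cortical task activity. Provides a synthetic-data generator
    with planted ground truth, task GLM estimation with motion censoring,
    PCA decomposition of voxel-by-task activity matrices with the CompW
    task-hub metric, principal-component-regression functional
    connectivity with participation-coefficient network-hub metrics,
    split-half cross-validated activity-flow mapping with null models and
    a noise ceiling, and virtual-lesion simulations with patient
    impairment classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
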