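Package: strokefc
Title: Resting-State Functional Connectivity and Lower-Limb Performance After Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline relating resting-state functional connectivity
    to lower-limb clinical performance in chronic stroke. Implements ROI-to-ROI
    Pearson/Fisher-z connectivity with hemispheric standardisation, edgewise
    linear-model screening under Benjamini-Hochberg false-discovery-rate
    control, threshold-sweep graph-theory metrics (nodal global efficiency,
    clustering coefficient, betweenness centrality) summarised by area under
    the metric-versus-threshold curve, repeated cross-validated elastic-net
    stability selection with a 90 percent selection-frequency rule, and
    corticospinal-tract-weighted lesion load. Ships a synthetic-cohort
    generator with planted ground truth (edge- and node-level effects, motion
    traces, lesion/tract mask pairs) so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
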