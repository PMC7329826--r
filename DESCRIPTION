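Package: dyadconn
Title: Dyadic Similarity of Resting-State Connectomes in Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing neural homophily: whether socially close
    individuals have more similar resting-state functional connectomes.
    Builds friendship graphs from roster-and-rating sociometric surveys,
    computes geodesic social distance and Louvain communities, derives
    per-subject parcellated connectivity matrices and Fisher-z inter-subject
    similarity, fits crossed-random-effects dyadic linear mixed models,
    pools cohorts by random-effects meta-analysis, characterises signed
    brain graphs (strength, diversity, modularity), predicts social
    distance from edgewise similarity with grouped elastic-net regression,
    and ships a synthetic-cohort generator with planted homophily for
    power and type-I calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    glmnet,
    metafor,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
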