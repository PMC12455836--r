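Package: molce
Title: Contrastive Explanations for Molecular Machine Learning Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates chemically conservative virtual analogues (foils) of
    test compounds by Bemis-Murcko scaffold and substituent replacement and
    quantifies the resulting contrastive shift in a classifier's probability
    distribution, explaining which structural features drive one prediction
    outcome over another. Includes reduced carbon-skeleton scaffold
    dictionaries, substituent pools, potency-based selectivity labeling,
    balanced random-forest modeling on circular fingerprints, applicability
    domain diagnostics, and a synthetic-library fixture generator with a
    closed-form toy classifier for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
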