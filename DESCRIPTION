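Package: abmlm
Title: Preferential Masking for Antibody Masked Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for training and analysing antibody masked language models
    (MLMs) with region-aware, non-uniform masking probabilities. Provides a
    synthetic paired heavy/light V(D)J repertoire generator with ground-truth
    framework/CDR annotations and controllable somatic hypermutation;
    alignment-based construction of per-residue region masks; a 26-token
    amino-acid vocabulary with paired-chain encoding; uniform and preferential
    masking-probability matrices with dynamic Bernoulli selection and 80/10/10
    token corruption; dataset construction utilities (deduplication, greedy
    identity clustering, splits, shuffled chain-pair generation, stratified
    cross-validation); a compact transformer encoder with rotary position
    embeddings, region-stratified evaluation and frozen-base classifier heads;
    binary classification metrics; and AttCAT gradient-based token attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'abmlm-package.R'
    'AllClasses.R'
    'germline.R'
    'repertoire.R'
    'annotation.R'
    'tokenization.R'
    'masking.R'
    'encoder.R'
    'backprop.R'
    'training.R'
    'classifier.R'
    'attribution.R'
    'dataset-ops.R'
    'metrics.R'
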