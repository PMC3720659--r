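Package: hergnet
Title: Drug Transcriptional-Response Networks for hERG Liability Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse compendia of drug-induced gene expression
    profiles for shared toxicity signatures. Implements batch mean-centering
    of log2 expression compendia, filtering of transcriptionally silent
    treatments, differential-expression masking against vehicle controls,
    affinity-propagation clustering of response profiles with hierarchical
    exemplar merging, permutation and hypergeometric enrichment of clusters
    for annotated hERG potassium-channel inhibitors, Tanimoto fingerprint
    comparisons, prediction statistics, and a synthetic compendium generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
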