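Package: lrrmap
Title: Entropy-Informed Segmentation Design and Binding-Hotspot Mapping
    for Modular Repeat Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Designs maximally informative sub-segmentation experiments for
    modular repeat proteins such as leucine-rich repeat (LRR) immune
    receptors, plans branch-and-bound refinement rounds with negative-evidence
    pruning, simulates ribosome-display qPCR binding readouts against planted
    paratopes, and analyses competed/uncompeted quantification-cycle (Cq)
    data (batch normalisation, delta-Cq with propagated uncertainty, Tukey
    fence outlier exclusion, one-way ANOVA with Tukey HSD) to call binding
    hotspots at repeat-unit resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
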