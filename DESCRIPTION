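Package: tissuetalk
Title: Ligand-Receptor Crosstalk Inference Between Tissues from Label-Free Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis chain for two-tissue, two-condition label-free
    quantitative proteomics: per-protein differential abundance on log2 LFQ
    intensities (Welch test, fold-change gating, volcano export), rule-based
    secretome calls from signal-peptide, non-classical-secretion and
    subcellular-localization annotations, ligand-receptor crosstalk candidate
    ranking via the change in a regularized product score (dLR) together with
    the change in summed log2 abundances (dSum), upstream-regulator activation
    z-scores with overlap enrichment and regulator-target network construction,
    and mapping of human genetic evidence (HuGE) scores to support tiers. A
    synthetic study generator with planted effects provides fully in-silico
    inputs and ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
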