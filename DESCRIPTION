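Package: argtrait
Title: Quantitative Trait Simulation on Ancestral Recombination Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quantitative traits directly on an ancestral
    recombination graph (ARG) encoded as succinct tree-sequence tables,
    without ever materialising a genotype matrix. Causal sites and alleles
    are drawn along the genome, effect sizes come from standard GWAS
    effect-size distributions (including a frequency-dependent alpha model
    and a multivariate normal for pleiotropy), genetic values are propagated
    through the local trees respecting back-mutations, aggregated additively
    per individual of arbitrary ploidy, and environmental noise calibrated
    to a requested narrow-sense heritability is added to produce phenotypes.
    Reads the tskit tabular format via a plain-text dialect or, when Python
    tskit is available, native .trees files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
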