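Package: restrictr
Title: Identification of Lineage-Restricted Genes from Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes whose expression is restricted to a single cell
    lineage (for example the vascular endothelium) by combining a replicated
    primary expression experiment with a reference compendium of other primary
    cell types. Implements lower-confidence-bound fold-change differential
    expression with a permutation estimate of the false discovery rate, a
    present/absent enrichment score, outlier-cluster classification, a
    composite rank score, and the downstream selection rule that yields a
    ranked restricted-gene table. Also provides gene-set over-representation
    with the conservative EASE variant of the Fisher exact test, a yes/no
    promoter-site enrichment gate, microRNA seed-match counting and
    enrichment, expression-pattern clustering, tissue-percentage tables, and
    a synthetic-data generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
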