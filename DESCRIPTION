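Package: orthoquartet
Title: Quartet-Based Orthology Inference from Pairwise Sequence Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers orthologous proteins across many genomes from all-vs-all
    similarity searches. Bidirectional best hits between species are screened
    for hidden gene-duplication events with an analytic quartet score computed
    from six pairwise bit-scores, avoiding explicit gene-tree reconstruction;
    pairs whose maximum score stays below a tunable cutoff are called
    orthologs, clustered into multi-species orthologous groups with a
    Markov-clustering engine, and annotated by consensus. Within-species
    inparalog groups extend pairwise orthology to many-to-many co-orthology.
    A gene-family duplication/loss simulator provides ground-truth labels for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
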