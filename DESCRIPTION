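Package: prionfam
Title: Prion-Like Composition and Domain Architecture in Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies conservation of prion-like composition and RRM domain
    architecture across protein ortholog families. Provides a table-driven
    log-likelihood-ratio scorer for prion-like (N/Q-rich) composition with a
    two-state run parse and a fixed-core-window score, a lowest-binomial-P
    compositional-bias scanner for Q, N and Q+N tracts, consolidation of
    curated and homology-derived domain annotations with greedy overlap
    resolution, decomposition of sequences into buffered inter-domain
    fragments for multi-domain counting, reciprocal-best-hit orthology and
    comparative paralog filters over tabular similarity data, family-level
    summary statistics, tree pruning utilities, and a synthetic ortholog
    family generator with planted domains and tracts for ground-truth
    validation.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
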