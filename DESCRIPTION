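Package: p53re
Title: Spacer-Aware Discovery and Chromatin-Context Analysis of p53 Response Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering p53 response elements (p53REs) in genomic
    sequence and relating their sequence strength to chromatin context. Builds
    position weight matrices from validated p53RE cores, scans genomes with a
    spacer-aware sliding window (spacers 0-3 nt, both strands, half-site
    concatenation, consensus-core prefilter), assigns the best element to each
    ChIP-seq peak, annotates elements with chromatin state, nearest gene,
    conservation, accessibility and transposable-element overlap, and computes
    decile and state-stratified summaries (group-mean regressions, fold-change
    classes, trend tests, TE family enrichment). Includes a seeded synthetic
    study generator that emulates the statistical couplings of a stress-induced
    p53 ChIP-seq experiment so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
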