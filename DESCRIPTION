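Package: colexnet
Title: Colexification Networks for Cross-Linguistic Semantic Typology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted colexification networks from multilingual
    wordlists and analyses their structure across language families and
    semantic domains. A colexification is the use of one word form for two
    distinct concepts (e.g. one word for both 'foot' and 'leg'). The package
    reads CLDF-style wordlist tables, applies dataset and concept inclusion
    filters, detects full colexifications per language variety, assembles
    global and per-family weighted networks, corrects colexification counts
    for shared inheritance by clustering word forms into cognate sets,
    detects network communities with Infomap and random-walk (walktrap)
    algorithms, compares community structure across families with the
    adjusted Rand index and exact adjusted mutual information, resamples
    weighted degrees across semantic domains, summarises perceptual-feature
    codings (contiguity, function, shape), and computes language-family
    homeland points by recursive spherical centroids. A synthetic wordlist
    generator with a ground-truth ledger makes every pipeline stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
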