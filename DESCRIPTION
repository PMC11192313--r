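Package: contagionPatterns
Title: Infection Patterns of Simple and Complex Contagion on Weighted
    Contact Networks and Hypergraphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted contact graphs and weighted hypergraphs from
    time-resolved face-to-face interaction records ("t i j" contact lists at
    fixed temporal resolution), simulates stochastic SIR/SEIR/COVID-like
    simple contagion, simplicial (higher-order) contagion and weighted
    threshold contagion on them, and summarises each process by its infection
    pattern: the directed matrix C whose entry C[i,j] is the probability,
    over stochastic realizations, that node i directly infected node j.
    Includes fractional infection attribution for complex contagion, basic
    reproduction number estimation and transmission-rate calibration,
    spreader/receiver node indices, attack-rate statistics and conditioning,
    cosine-similarity comparison of infection patterns, and a synthetic
    generator of school-like contact data with community structure,
    heavy-tailed contact counts and correlated link/triad weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
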