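Package: hubrank
Title: Hub Node Ranking and Essentiality Benchmarking for Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks nodes of undirected biological networks (for example
    protein-protein interaction networks) with eleven topological scoring
    methods: four local methods (Degree, MNC, DMNC, MCC) and seven global
    methods (Closeness, EcCentricity, Radiality, BottleNeck, Stress,
    Betweenness, EPC), with per-component handling so disconnected networks
    can be scored. Includes ranked top-k subnetwork extraction with
    first-stage neighbour expansion and abstract shortest-path edges, an
    essential-node benchmark (degree-threshold partition, precision at k,
    method overlap, low-degree capture), a seeded clique-planting fixture
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    optparse,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
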