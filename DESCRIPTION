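Package: adiponet
Title: Typed Signed Directed Networks of Adipokine Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construct, validate and analyze layered signed directed
    networks that trace information flow from physiologic perturbations
    and sleep disturbances through adipokines and their molecular targets
    to physiologic functions and disease processes. Networks are built
    from curated assertion tables under a closed six-category transition
    schema. Degree and betweenness centrality (Brandes' shortest-path
    counting algorithm, with an independent brute-force enumeration
    oracle) feed hub, bottleneck and nonhub-bottleneck classification.
    Includes a seeded generator of synthetic layered networks with
    planted hubs and a planted bridge target, edge-resampling robustness
    analysis of centrality-based classifications, GEXF/GraphML export
    for Gephi, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
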