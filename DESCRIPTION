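Package: herbnet
Title: Network-Pharmacology Target-Axis Inference from Multi-Group
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers candidate therapeutic target axes for herb-pair
    combinations from five-group expression profiling. Screens
    differentially expressed genes between treatment and model groups,
    classifies genes into six direction-reversal combination categories,
    builds a score-thresholded gene interaction network, prioritizes hubs
    and major hubs by four topological features (degree, betweenness,
    closeness, k-coreness), partitions the hub network into functional
    modules by Markov clustering, performs hypergeometric pathway
    over-representation with Bonferroni correction, and extracts a
    seed-anchored shortest-path signal axis between a combination-related
    gene and a known therapeutic target. Ships a synthetic-data generator
    with planted ground truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
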