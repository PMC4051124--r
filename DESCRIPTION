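Package: geneconnectome
Title: Gene Prioritization by Biological Distance in Weighted Interaction Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a weighted gene network from pairwise interaction
    confidence scores, inverts the scores into biological distances, and
    computes gene-specific connectomes: every other gene ranked by its
    shortest-path biological distance to a core gene, annotated with rank,
    connectivity p-value, best reciprocal p-value, distance ratios, sphere,
    predicted route, degrees of separation and full gene name. Candidate
    gene lists from high-throughput experiments (for example filtered
    whole-exome sequencing variants) can be prioritized against one or more
    core genes by distance, p-value or best reciprocal p-value, globally or
    per core gene. Includes the standard variant-frequency filtering stage,
    a seeded synthetic-data generator with planted pathway modules for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
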