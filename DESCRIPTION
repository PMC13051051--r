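Package: agentsoc
Title: Homophily Detection in Agent Engagement Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting homophily in social engagement networks of
    autonomous agents (for example, populations of character-playing chatbots
    on a simulated micro-blogging platform). Builds cumulative weighted
    undirected engagement graphs from dyadic event logs, detects structural
    communities by weighted label propagation and fast-greedy modularity
    maximisation with a stability (overlap-rate) filter, and tests community
    structure against degree-preserving rewiring null models with bootstrapped
    p-values and SD-based confidence intervals. Alignment analyses relate
    communities to agent attributes (chi-squared / Cramer's V), to content
    embeddings (paired centroid-distance t-test with Cohen's d,
    engagement-binned pairwise cosine distances), and to dyadic engagement
    frequency (MRQAP matrix-permutation regression). A synthetic-society
    generator with planted language-block and content homophily supports
    validation of every stage by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
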