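Package: comorbnet
Title: Multimorbidity Networks Under Alternative Disease Co-Occurrence Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs weighted, undirected disease co-occurrence (multimorbidity)
    networks from person-level chronic-condition data under seven association
    measures derived from the 2x2 contingency table (lift, relative risk, phi,
    Jaccard, cosine, Kulczynski, joint prevalence), applies support, significance
    and positivity filters to candidate disease dyads, detects communities with
    the weighted Louvain algorithm, and quantifies how the choice of measure
    changes network structure (density, central nodes, community partitions,
    edge composition by prevalence band). Includes a seedable synthetic-cohort
    generator with a controlled prevalence spectrum and planted co-occurrence
    blocks for benchmarking the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
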