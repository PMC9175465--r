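#!/usr/bin/env Rscript
# Step 5: cross-measure network comparison.
#
# For each edge stratum, compares the seven measure-specific networks on
# community structure (ARI over shared nodes), edges in common, and top-20
# central-node agreement, and writes the matrices plus median (Q1-Q3)
# roll-ups as JSON.

suppressPackageStartupMessages(library(comorbnet))

assoc <- read_association_csv("results/associations.csv")
prev_df <- read.csv("results/prevalence.csv")
prevalence <- setNames(prev_df$prevalence, prev_df$condition)
seed <- 1L

strata <- list(list(type = "all"),
               list(type = "top_fraction", f = 0.5),
               list(type = "top_k", k = 200))
for (s in strata) {
  sid <- comorbnet:::stratum_id(s)
  nets <- lapply(setNames(measure_names(), measure_names()), function(m) {
    build_network(assoc, m, s$type,
                  f = if (is.null(s$f)) 0.5 else s$f,
                  k = if (is.null(s$k)) 200 else s$k,
                  prevalence = prevalence)
  })
  parts <- lapply(nets, detect_communities, seed = seed)
  report <- build_comparison_report(nets, parts, k = 20)
  write_comparison_json(report, sprintf("results/comparison_%s.json", sid))
  message(sprintf("--- stratum: %s ---", sid))
  print(report)
}
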