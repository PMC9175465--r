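#!/usr/bin/env Rscript
# Step 4: community structure.
#
# Runs weighted Louvain community detection on every (measure, stratum)
# network and records the number of communities and modularity; writes one
# partition CSV per network.

suppressPackageStartupMessages(library(comorbnet))

assoc <- read_association_csv("results/associations.csv")
prev_df <- read.csv("results/prevalence.csv")
prevalence <- setNames(prev_df$prevalence, prev_df$condition)
seed <- 1L

strata <- list(list(type = "all"),
               list(type = "top_fraction", f = 0.5),
               list(type = "top_k", k = 200))
rows <- list()
for (s in strata) {
  sid <- comorbnet:::stratum_id(s)
  for (m in measure_names()) {
    net <- build_network(assoc, m, s$type,
                         f = if (is.null(s$f)) 0.5 else s$f,
                         k = if (is.null(s$k)) 200 else s$k,
                         prevalence = prevalence)
    part <- detect_communities(net, seed = seed)
    write_partition_csv(part, sprintf("results/partition_%s_%s.csv", m, sid))
    rows[[paste(m, sid)]] <- data.frame(
      measure = m, stratum = sid,
      n_communities = part$n_communities,
      modularity = part$modularity
    )
  }
}
summary <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(summary, "results/community_summary.csv", row.names = FALSE)
message("community structure by measure and stratum:")
print(summary)
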