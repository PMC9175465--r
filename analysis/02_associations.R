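#!/usr/bin/env Rscript
# Step 2: disease association analysis.
#
# Reads the long-format cohort, enumerates all condition dyads, applies the
# support (joint frequency >= 15), significance (alpha = 0.01, chi-square or
# Fisher exact by the Cochran rule) and positivity (phi > 0) filters, and
# computes all seven co-occurrence measures for the retained dyads.

suppressPackageStartupMessages(library(comorbnet))

cohort <- read_cohort("results/cohort_long.csv", format = "long")
assoc <- build_association_table(cohort, min_support = 15, alpha = 0.01)
acc <- association_accounting(assoc)
message(sprintf(
  "Out of %d pairwise disease co-occurrences with joint frequencies >= 15, %d (%.1f%%) were excluded; %d associations remained.",
  acc$n_candidates, acc$n_excluded, 100 * acc$n_excluded / acc$n_candidates,
  acc$n_retained
))
write_association_csv(assoc, "results/associations.csv")
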