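# Independent brute-force oracles. These recompute quantities from first
# principles (per-person loops, direct formulas, exhaustive search) and are
# deliberately kept separate from the package's vectorized code paths.

# Contingency cells for two indicator vectors by looping over persons.
oracle_cells <- function(x, y) {
  a <- b <- cc <- d <- 0
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) a <- a + 1
    else if (x[i] == 1) b <- b + 1
    else if (y[i] == 1) cc <- cc + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = cc, d = d, n = length(x))
}

# All seven measures straight from their definitions on raw indicators.
oracle_measures <- function(x, y) {
  z <- oracle_cells(x, y)
  a <- z["a"]; b <- z["b"]; cc <- z["c"]; d <- z["d"]; n <- z["n"]
  rr1 <- if (cc > 0) (a / (a + b)) / (cc / (cc + d)) else Inf
  rr2 <- if (b > 0) (a / (a + cc)) / (b / (b + d)) else Inf
  unname_all <- function(v) stats::setNames(as.numeric(v), NULL)
  c(lift = unname_all((a / n) / ((a + b) / n * (a + cc) / n)),
    relative_risk = unname_all(max(rr1, rr2)),
    phi = unname_all((a * d - b * cc) /
                       sqrt((a + b) * (a + cc) * (b + d) * (cc + d))),
    jaccard = unname_all(a / (a + b + cc)),
    cosine = unname_all(a / sqrt((a + b) * (a + cc))),
    kulczynski = unname_all(mean(c(a / (a + b), a / (a + cc)))),
    joint_prevalence = unname_all(a / n))
}

# Random cohort with no planted structure.
random_cohort <- function(n, k, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * k, 1, p), nrow = n)
    colnames(m) <- sprintf("X%02d", seq_len(k))
    cohort_matrix(m)
  })
}

# Build a disease_network directly from an edge data frame (for graph-level
# unit tests that do not need a cohort).
toy_network <- function(edges, prevalence, measure = "phi",
                        selection = "all") {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  pv <- prevalence[igraph::V(g)$name]
  igraph::V(g)$prevalence <- unname(pv)
  igraph::V(g)$band <- as.character(prevalence_band(pv))
  if (is.null(edges$joint_prevalence)) igraph::E(g)$joint_prevalence <- 0.01
  if (is.null(edges$prevalence_difference)) {
    ends <- igraph::as_edgelist(g, names = TRUE)
    igraph::E(g)$prevalence_difference <- abs(pv[ends[, 1]] - pv[ends[, 2]])
  }
  structure(list(graph = g, measure = measure,
                 selection = list(type = selection)),
            class = "disease_network")
}

# Exhaustive maximum-modularity partition by enumerating all partitions of
# <= 9 nodes via restricted growth strings.
oracle_best_partition <- function(net) {
  nodes <- igraph::V(net$graph)$name
  n <- length(nodes)
  stopifnot(n <= 9)
  best_q <- -Inf
  best <- NULL
  grow <- function(assign, next_id) {
    i <- length(assign) + 1
    if (i > n) {
      part <- as_partition_oracle(stats::setNames(assign, nodes))
      q <- modularity_score(net, part)
      if (q > best_q) {
        best_q <<- q
        best <<- part
      }
      return(invisible())
    }
    for (id in seq_len(next_id)) {
      grow(c(assign, id), max(next_id, id + 1))
    }
  }
  grow(integer(0), 1)
  list(partition = best, modularity = best_q)
}

# Minimal partition constructor mirroring the exported class contract.
as_partition_oracle <- function(assignment) {
  nodes <- sort(names(assignment))
  ids <- assignment[nodes]
  relabeled <- as.integer(factor(ids, levels = unique(ids))) - 1L
  structure(list(assignment = stats::setNames(relabeled, nodes),
                 n_communities = length(unique(relabeled)),
                 modularity = NA_real_),
            class = "partition")
}
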