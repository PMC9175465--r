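#' Detect communities with the weighted Louvain algorithm
#'
#' Runs the multi-level greedy modularity optimization of Blondel et al.
#' (Louvain) on the weighted, undirected disease network and returns the
#' final-level, non-overlapping partition. The node-visit order is
#' randomized, so a seed fixes the result; infinite edge weights (possible
#' for relative risk with a zero-denominator direction) are replaced, for
#' community detection only, by ten times the largest finite weight in the
#' network so that their dominance is preserved on a finite scale.
#'
#' @param net a [build_network()] result.
#' @param seed integer RNG seed.
#' @param resolution Louvain resolution parameter (default 1, the original
#'   algorithm).
#' @param n_restarts number of runs; the partition with the highest
#'   modularity is kept (default 1, a single run).
#' @return list of class `partition` with elements `assignment` (named
#'   integer vector, community ids contiguous from 0), `n_communities` and
#'   `modularity`.
#' @export
detect_communities <- function(net, seed = 1L, resolution = 1.0,
                               n_restarts = 1L) {
  stopifnot(inherits(net, "disease_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  w <- igraph::E(g)$weight
  if (any(is.na(w)) || any(w < 0)) stop("edge weights must be nonnegative")
  if (any(is.infinite(w))) {
    w[is.infinite(w)] <- 10 * max(w[is.finite(w)], 1)
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
      memb <- igraph::membership(cl)
      part <- as_partition(stats::setNames(as.integer(memb), names(memb)))
      part$modularity <- modularity_score(net, part, weights = w)
      if (is.null(best) || part$modularity > best$modularity) best <- part
    }
  })
  best
}

# Normalize an assignment to contiguous 0-based ids in order of first
# appearance over the (sorted) node labels.
as_partition <- function(assignment) {
  nodes <- sort(names(assignment))
  ids <- assignment[nodes]
  relabeled <- as.integer(factor(ids, levels = unique(ids))) - 1L
  structure(
    list(assignment = stats::setNames(relabeled, nodes),
         n_communities = length(unique(relabeled)),
         modularity = NA_real_),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities (Q = %.4f)\n",
              length(x$assignment), x$n_communities, x$modularity))
  invisible(x)
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ W_c / W - (S_c / 2W)^2 ]` where `W` is the total edge
#' weight, `W_c` the intra-community weight of community `c` and `S_c` the
#' summed strength of its nodes.
#'
#' @param net a [build_network()] result.
#' @param partition a `partition` covering every node of `net`.
#' @param weights optional replacement edge-weight vector (used internally
#'   to score with infinite weights mapped to a finite scale).
#' @return modularity in \[-0.5, 1\].
#' @export
modularity_score <- function(net, partition, weights = NULL) {
  stopifnot(inherits(net, "disease_network"), inherits(partition, "partition"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(partition$assignment))) {
    stop("partition does not cover every network node")
  }
  memb <- partition$assignment[nodes]
  w <- if (is.null(weights)) igraph::E(g)$weight else weights
  ends <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(ends) == 0) return(0)
  total <- sum(w)
  c1 <- memb[ends[, 1]]
  c2 <- memb[ends[, 2]]
  intra <- tapply(w[c1 == c2], c1[c1 == c2], sum)
  strength <- tapply(c(w, w), c(c1, c2), sum)     # S_c: each edge counts at both ends
  q <- sum(intra) / total - sum((strength / (2 * total))^2)
  unname(q)
}
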