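#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement,
#' `ARI = (Index - ExpectedIndex) / (MaxIndex - ExpectedIndex)`, computed
#' from the contingency table of the two assignments restricted to `scope`.
#' Equals 1 for identical partitions and is approximately 0 for independent
#' ones. Because top-k networks built with different measures can have
#' different node sets, the default scope is the intersection of the two
#' assignments' node sets.
#'
#' @param p1,p2 `partition` objects (or bare named assignment vectors).
#' @param scope node labels on which to compare; defaults to the
#'   intersection of the two node sets.
#' @return the ARI, at most 1.
#' @export
adjusted_rand_index <- function(p1, p2, scope = NULL) {
  a1 <- if (inherits(p1, "partition")) p1$assignment else p1
  a2 <- if (inherits(p2, "partition")) p2$assignment else p2
  if (is.null(scope)) scope <- intersect(names(a1), names(a2))
  if (length(scope) < 2) stop("ARI undefined on fewer than 2 shared nodes")
  if (!all(scope %in% names(a1)) || !all(scope %in% names(a2))) {
    stop("both partitions must cover the scope")
  }
  tab <- table(a1[scope], a2[scope])
  n <- length(scope)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  expected <- sum_i * sum_j / choose2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)      # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Percent of edges in common between two networks
#'
#' Edges are compared as unordered label pairs. The denominator is the
#' common edge count when the two networks have equally many edges (the
#' usual case when both were built under the same stratum) and the smaller
#' edge count otherwise.
#'
#' @param n1,n2 [build_network()] results.
#' @return agreement in percent, in \[0, 100\].
#' @export
edge_agreement <- function(n1, n2) {
  stopifnot(inherits(n1, "disease_network"), inherits(n2, "disease_network"))
  key <- function(net) {
    ends <- igraph::as_edgelist(net$graph, names = TRUE)
    if (nrow(ends) == 0) stop("network has no edges")
    paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]), sep = "\r")
  }
  e1 <- key(n1)
  e2 <- key(n2)
  denom <- min(length(e1), length(e2))
  100 * length(intersect(e1, e2)) / denom
}

#' Percent agreement on the top-k central nodes
#'
#' @param list1,list2 ordered top-k node lists from [top_central_nodes()].
#' @param k the nominal list length (default 20); the denominator.
#' @return agreement in percent.
#' @export
central_node_agreement <- function(list1, list2, k = 20) {
  if (k < 1) stop("k must be at least 1")
  100 * length(intersect(list1, list2)) / k
}

#' Compare the networks built under all measures
#'
#' Fills symmetric 7x7 (or however many measures are supplied) matrices of
#' community-structure similarity (ARI on the intersection of node sets),
#' edge agreement and top-k central-node agreement over every measure pair,
#' with per-network summaries and median (Q1-Q3) roll-ups over the
#' off-diagonal pairs.
#'
#' @param networks named list of [build_network()] results, one per
#'   measure, all built under the same selection stratum.
#' @param partitions named list of [detect_communities()] results aligned
#'   with `networks`.
#' @param k top-central-node list length (default 20).
#' @return list of class `comparison_report` with elements `measures`,
#'   `ari_matrix`, `edge_agreement_matrix`, `centrality_agreement_matrix`,
#'   `summaries` and `per_network`.
#' @export
build_comparison_report <- function(networks, partitions, k = 20) {
  ms <- names(networks)
  stopifnot(length(ms) >= 2, setequal(ms, names(partitions)))
  strata <- unique(vapply(networks, function(x) x$selection$type, ""))
  if (length(strata) != 1) {
    stop("all networks must be built under the same selection stratum")
  }
  nm <- length(ms)
  ari <- matrix(1, nm, nm, dimnames = list(ms, ms))
  edge <- matrix(100, nm, nm, dimnames = list(ms, ms))
  cent <- matrix(100, nm, nm, dimnames = list(ms, ms))
  top_nodes <- lapply(networks, top_central_nodes, k = k)
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      ari[i, j] <- ari[j, i] <-
        adjusted_rand_index(partitions[[ms[i]]], partitions[[ms[j]]])
      edge[i, j] <- edge[j, i] <-
        edge_agreement(networks[[ms[i]]], networks[[ms[j]]])
      cent[i, j] <- cent[j, i] <-
        central_node_agreement(top_nodes[[ms[i]]], top_nodes[[ms[j]]], k = k)
    }
  }
  offdiag <- function(m) m[upper.tri(m)]
  summary3 <- function(v) {
    q <- stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    stats::setNames(q, c("median", "q1", "q3"))
  }
  per_network <- do.call(rbind, lapply(ms, function(nm_i) {
    net <- networks[[nm_i]]
    data.frame(
      measure = nm_i,
      n_nodes = igraph::vcount(net$graph),
      n_edges = igraph::ecount(net$graph),
      density = network_density(net),
      n_communities = partitions[[nm_i]]$n_communities,
      modularity = partitions[[nm_i]]$modularity,
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      measures = ms,
      ari_matrix = ari,
      edge_agreement_matrix = edge,
      centrality_agreement_matrix = cent,
      summaries = list(
        ari = summary3(offdiag(ari)),
        edge_agreement = summary3(offdiag(edge)),
        centrality_agreement = summary3(offdiag(cent))
      ),
      per_network = per_network
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d measures, stratum-matched networks\n",
              length(x$measures)))
  s <- x$summaries
  cat(sprintf("  ARI: median %.2f (Q1-Q3 %.2f-%.2f)\n",
              s$ari["median"], s$ari["q1"], s$ari["q3"]))
  cat(sprintf("  edge agreement: median %.1f%% (%.1f-%.1f)\n",
              s$edge_agreement["median"], s$edge_agreement["q1"],
              s$edge_agreement["q3"]))
  cat(sprintf("  central-node agreement: median %.1f%% (%.1f-%.1f)\n",
              s$centrality_agreement["median"], s$centrality_agreement["q1"],
              s$centrality_agreement["q3"]))
  print(x$per_network)
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param report a [build_comparison_report()] result.
#' @param path output path.
#' @export
write_comparison_json <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(
    list(
      measures = report$measures,
      ari_matrix = report$ari_matrix,
      edge_agreement_matrix = report$edge_agreement_matrix,
      centrality_agreement_matrix = report$centrality_agreement_matrix,
      summaries = report$summaries,
      per_network = report$per_network
    ),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}
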