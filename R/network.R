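#' Build a weighted disease network from an association table
#'
#' Edges are the retained dyads of the association table, weighted by the
#' chosen co-occurrence measure and ranked by weight descending. Three edge
#' strata are supported: `"all"` keeps every retained association,
#' `"top_fraction"` keeps the strongest `floor(f * m)` of the `m` retained
#' associations, and `"top_k"` keeps the strongest `min(k, m)`. Ties at the
#' cut-off are broken deterministically by pair label, ascending, so the
#' stratum size is exact. Infinite relative-risk weights rank above every
#' finite weight. Nodes enter the network only as edge endpoints; each
#' carries its cohort prevalence and prevalence band.
#'
#' @param assoc an [build_association_table()] result.
#' @param measure one of [measure_names()].
#' @param selection `"all"`, `"top_fraction"` or `"top_k"`.
#' @param f fraction kept under `"top_fraction"` (default 0.5).
#' @param k edge count kept under `"top_k"` (default 200).
#' @param prevalence named numeric vector of per-condition prevalence
#'   covering every condition appearing in `assoc`.
#' @param band_thresholds prevalence band cut-points (default 1% and 7%).
#' @return an object of class `disease_network` wrapping an
#'   \pkg{igraph} graph (element `graph`) with vertex attributes
#'   `prevalence` and `band` and edge attributes `weight`,
#'   `joint_prevalence` and `prevalence_difference`; elements `measure` and
#'   `selection` record how it was built.
#' @export
build_network <- function(assoc, measure, selection = c("all", "top_fraction", "top_k"),
                          f = 0.5, k = 200, prevalence,
                          band_thresholds = c(0.01, 0.07)) {
  stopifnot(inherits(assoc, "association_table"))
  if (!measure %in% measure_names()) {
    stop(sprintf("unknown measure: %s", measure))
  }
  selection <- match.arg(selection)
  missing_prev <- setdiff(unique(c(assoc$pair_x, assoc$pair_y)),
                          names(prevalence))
  if (length(missing_prev) > 0) {
    stop(sprintf("prevalence missing for conditions: %s",
                 paste(utils::head(missing_prev, 5), collapse = ", ")))
  }
  w <- assoc[[measure]]
  ord <- order(-w, assoc$pair_x, assoc$pair_y)
  m <- nrow(assoc)
  n_keep <- switch(selection,
                   all = m,
                   top_fraction = floor(f * m),
                   top_k = min(k, m))
  kept <- assoc[ord[seq_len(n_keep)], , drop = FALSE]

  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$pair_x, to = kept$pair_y,
               weight = kept[[measure]],
               joint_prevalence = kept$joint_prevalence,
               prevalence_difference = abs(prevalence[kept$pair_x] -
                                             prevalence[kept$pair_y]),
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  pv <- prevalence[igraph::V(g)$name]
  igraph::V(g)$prevalence <- unname(pv)
  igraph::V(g)$band <- as.character(prevalence_band(pv, band_thresholds))
  structure(
    list(graph = g, measure = measure,
         selection = list(type = selection,
                          f = if (selection == "top_fraction") f else NULL,
                          k = if (selection == "top_k") k else NULL)),
    class = "disease_network"
  )
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf(
    "<disease_network> measure=%s selection=%s: %d nodes, %d edges, density %.3f\n",
    x$measure, x$selection$type, igraph::vcount(x$graph),
    igraph::ecount(x$graph),
    if (igraph::vcount(x$graph) >= 2) network_density(x) else NA_real_
  ))
  invisible(x)
}

#' Network density
#'
#' The ratio of the number of edges present to the number of possible edges
#' between all node pairs, `m / (v(v-1)/2)`.
#'
#' @param net a [build_network()] result, or a node count when `m` is given.
#' @param m edge count (closed-form use).
#' @return density in \[0, 1\].
#' @export
network_density <- function(net, m = NULL) {
  if (inherits(net, "disease_network")) {
    v <- igraph::vcount(net$graph)
    m <- igraph::ecount(net$graph)
  } else {
    v <- net
    if (is.null(m)) stop("supply an edge count m with a node count")
  }
  if (v < 2) stop("density undefined for fewer than 2 nodes")
  m / (v * (v - 1) / 2)
}

#' Degree centrality
#'
#' Unweighted incident-edge count per node (the edge weights play no role).
#'
#' @param net a [build_network()] result.
#' @return named integer vector of node degrees.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  if (igraph::vcount(net$graph) == 0) stop("empty network")
  igraph::degree(net$graph)
}

#' Top central nodes by degree
#'
#' @param net a [build_network()] result.
#' @param k number of nodes to return (default 20); ties broken by label
#'   ascending so the output is deterministic.
#' @return character vector of `min(k, v)` node labels ordered by degree
#'   descending then label ascending.
#' @export
top_central_nodes <- function(net, k = 20) {
  if (k < 1) stop("k must be at least 1")
  deg <- degree_centrality(net)
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(min(k, length(deg)))]
}

#' Edge composition by prevalence band
#'
#' Classifies every edge by the unordered prevalence-band pair of its
#' endpoints (low < 1%, moderate 1 to < 7%, high >= 7%) and summarizes the
#' distributions of edge joint prevalence and absolute prevalence
#' difference as median (Q1-Q3), in percent.
#'
#' @param net a [build_network()] result (nodes carry `prevalence` and
#'   `band` attributes).
#' @return list of class `edge_profile` with `band_pair_percentages` (named
#'   numeric summing to 100 over the six band pairs), and
#'   `joint_prevalence_summary` / `prevalence_difference_summary`, each a
#'   named vector `(median, q1, q3)` in percent.
#' @export
edge_profile <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  g <- net$graph
  if (is.null(igraph::V(g)$prevalence) || any(is.na(igraph::V(g)$prevalence))) {
    stop("every node must have a prevalence attribute")
  }
  ends <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(ends) == 0) stop("network has no edges")
  band <- stats::setNames(igraph::V(g)$band, igraph::V(g)$name)
  lv <- c("low", "moderate", "high")
  b1 <- factor(band[ends[, 1]], levels = lv)
  b2 <- factor(band[ends[, 2]], levels = lv)
  lo <- pmin(as.integer(b1), as.integer(b2))
  hi <- pmax(as.integer(b1), as.integer(b2))
  pair_class <- factor(
    paste(lv[hi], lv[lo], sep = "-"),
    levels = c("low-low", "moderate-low", "moderate-moderate",
               "high-low", "high-moderate", "high-high")
  )
  pct <- 100 * table(pair_class) / length(pair_class)
  summary3 <- function(v) {
    q <- stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    stats::setNames(100 * q, c("median", "q1", "q3"))
  }
  structure(
    list(
      band_pair_percentages = stats::setNames(as.numeric(pct), names(pct)),
      joint_prevalence_summary = summary3(igraph::E(g)$joint_prevalence),
      prevalence_difference_summary = summary3(igraph::E(g)$prevalence_difference)
    ),
    class = "edge_profile"
  )
}

#' @export
print.edge_profile <- function(x, ...) {
  cat("<edge_profile>\n  band pair percentages:\n")
  for (nm in names(x$band_pair_percentages)) {
    cat(sprintf("    %-18s %5.1f%%\n", nm, x$band_pair_percentages[[nm]]))
  }
  cat(sprintf("  joint prevalence: %.1f%% (%.1f-%.1f)\n",
              x$joint_prevalence_summary["median"],
              x$joint_prevalence_summary["q1"],
              x$joint_prevalence_summary["q3"]))
  cat(sprintf("  prevalence difference: %.1f%% (%.1f-%.1f)\n",
              x$prevalence_difference_summary["median"],
              x$prevalence_difference_summary["q1"],
              x$prevalence_difference_summary["q3"]))
  invisible(x)
}

#' Export a disease network
#'
#' `write_graphml()` uses the \pkg{igraph} GraphML writer; `write_gexf()`
#' emits minimal GEXF 1.2 with the same node and edge attributes;
#' `write_edgelist_csv()` writes a flat CSV mirror.
#'
#' @param net a [build_network()] result.
#' @param path output file path.
#' @rdname network_export
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname network_export
#' @export
write_gexf <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  g <- net$graph
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  vnames <- igraph::V(g)$name
  nodes <- sprintf(
    '      <node id="%s" label="%s">\n        <attvalues><attvalue for="0" value="%.10g"/><attvalue for="1" value="%s"/></attvalues>\n      </node>',
    esc(vnames), esc(vnames), igraph::V(g)$prevalence, igraph::V(g)$band
  )
  ends <- igraph::as_edgelist(g, names = TRUE)
  edges <- sprintf(
    '      <edge id="%d" source="%s" target="%s" weight="%.10g">\n        <attvalues><attvalue for="2" value="%.10g"/><attvalue for="3" value="%.10g"/></attvalues>\n      </edge>',
    seq_len(nrow(ends)) - 1L, esc(ends[, 1]), esc(ends[, 2]),
    igraph::E(g)$weight, igraph::E(g)$joint_prevalence,
    igraph::E(g)$prevalence_difference
  )
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="prevalence" type="double"/>',
    '      <attribute id="1" title="band" type="string"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="2" title="joint_prevalence" type="double"/>',
    '      <attribute id="3" title="prevalence_difference" type="double"/>',
    '    </attributes>',
    '    <nodes>', nodes, '    </nodes>',
    '    <edges>', edges, '    </edges>',
    '  </graph>', '</gexf>'
  )
  writeLines(xml, path)
  invisible(path)
}

#' @rdname network_export
#' @export
write_edgelist_csv <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  ends <- igraph::as_edgelist(net$graph, names = TRUE)
  utils::write.csv(
    data.frame(from = ends[, 1], to = ends[, 2],
               weight = igraph::E(net$graph)$weight,
               joint_prevalence = igraph::E(net$graph)$joint_prevalence,
               prevalence_difference = igraph::E(net$graph)$prevalence_difference,
               stringsAsFactors = FALSE),
    path, row.names = FALSE
  )
  invisible(path)
}
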