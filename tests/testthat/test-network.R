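# small association table + prevalence shared across network tests
make_test_assoc <- function(n = 400, k = 8, seed = 21) {
  coh <- random_cohort(n, k, p = 0.35, seed = seed)
  list(cohort = coh,
       assoc = build_association_table(coh, min_support = 5, alpha = 0.9))
}

test_that("edge strata keep the documented edge counts", {
  ta <- make_test_assoc()
  m <- nrow(ta$assoc)
  expect_gt(m, 10)
  net_all <- build_network(ta$assoc, "phi", "all", prevalence = ta$cohort$prevalence)
  expect_equal(igraph::ecount(net_all$graph), m)
  net_half <- build_network(ta$assoc, "phi", "top_fraction", f = 0.5,
                            prevalence = ta$cohort$prevalence)
  expect_equal(igraph::ecount(net_half$graph), floor(0.5 * m))
  net_top <- build_network(ta$assoc, "phi", "top_k", k = m + 50,
                           prevalence = ta$cohort$prevalence)
  expect_equal(igraph::ecount(net_top$graph), m)   # min(k, m) rule
  net_5 <- build_network(ta$assoc, "phi", "top_k", k = 5,
                         prevalence = ta$cohort$prevalence)
  expect_equal(igraph::ecount(net_5$graph), 5)
  expect_error(build_network(ta$assoc, "odds_ratio", "all",
                             prevalence = ta$cohort$prevalence),
               "unknown measure")
})

test_that("top-k edges are the k strongest, nested across k, nodes enter via edges", {
  ta <- make_test_assoc()
  prev <- ta$cohort$prevalence
  edge_keys <- function(net) {
    e <- igraph::as_edgelist(net$graph, names = TRUE)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  k_seq <- c(3, 8, 15)
  nets <- lapply(k_seq, function(k) {
    build_network(ta$assoc, "jaccard", "top_k", k = k, prevalence = prev)
  })
  # nesting under the deterministic tie rule
  expect_true(all(edge_keys(nets[[1]]) %in% edge_keys(nets[[2]])))
  expect_true(all(edge_keys(nets[[2]]) %in% edge_keys(nets[[3]])))
  # kept weights dominate dropped weights
  w_sorted <- sort(ta$assoc$jaccard, decreasing = TRUE)
  expect_equal(sort(igraph::E(nets[[2]]$graph)$weight, decreasing = TRUE),
               w_sorted[1:8])
  # no isolated nodes
  expect_true(all(igraph::degree(nets[[1]]$graph) > 0))
  # no self loops or duplicate edges
  expect_false(igraph::any_loop(nets[[3]]$graph))
  expect_false(igraph::any_multiple(nets[[3]]$graph))
})

test_that("infinite relative-risk weights rank above all finite weights", {
  assoc <- structure(
    data.frame(pair_x = c("A", "A", "B"), pair_y = c("B", "C", "C"),
               a = c(20, 18, 16), b = c(0, 5, 6), c = c(0, 4, 7),
               d = c(80, 73, 71), n = 100,
               test_used = "fisher_exact", p_value = 1e-6,
               lift = c(5, 3, 2), relative_risk = c(Inf, 4, 3),
               phi = c(1, 0.5, 0.4), jaccard = c(1, 0.6, 0.5),
               cosine = c(1, 0.7, 0.6), kulczynski = c(1, 0.7, 0.6),
               joint_prevalence = c(0.2, 0.18, 0.16),
               stringsAsFactors = FALSE),
    class = c("association_table", "data.frame"),
    n_candidates = 3L, n_excluded = 0L,
    filter_params = list(min_support = 15, alpha = 0.01))
  prev <- c(A = 0.2, B = 0.2, C = 0.22)
  net <- build_network(assoc, "relative_risk", "top_k", k = 1, prevalence = prev)
  e <- igraph::as_edgelist(net$graph, names = TRUE)
  expect_equal(sort(as.character(e[1, ])), c("A", "B"))
  expect_identical(igraph::E(net$graph)$weight, Inf)
})

test_that("network density matches the closed form and igraph", {
  expect_equal(network_density(2, 1), 1.0)
  ta <- make_test_assoc()
  net <- build_network(ta$assoc, "cosine", "top_k", k = 12,
                       prevalence = ta$cohort$prevalence)
  v <- igraph::vcount(net$graph)
  expect_equal(network_density(net), 12 / (v * (v - 1) / 2))
  expect_equal(network_density(net), igraph::edge_density(net$graph))
  expect_lte(network_density(net), 1)
  expect_error(network_density(1, 0), "fewer than 2")
})

test_that("degree centrality and top central nodes follow the tie rules", {
  tri <- toy_network(data.frame(from = c("a", "b", "c"),
                                to = c("b", "c", "a"), weight = 1),
                     prevalence = c(a = 0.1, b = 0.1, c = 0.1))
  expect_equal(unname(degree_centrality(tri)), c(2, 2, 2))
  expect_equal(top_central_nodes(tri, k = 3), c("a", "b", "c"))  # lexicographic ties
  star <- toy_network(data.frame(from = "hub", to = paste0("leaf", 1:5),
                                 weight = 1),
                      prevalence = setNames(rep(0.05, 6),
                                            c("hub", paste0("leaf", 1:5))))
  deg <- degree_centrality(star)
  expect_equal(unname(deg["hub"]), 5)
  expect_equal(top_central_nodes(star, k = 1), "hub")
  expect_length(top_central_nodes(star, k = 50), 6)   # k > v returns all
  # adjacency-matrix oracle on a random graph
  ta <- make_test_assoc(seed = 63)
  net <- build_network(ta$assoc, "lift", "all", prevalence = ta$cohort$prevalence)
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  expect_equal(degree_centrality(net)[rownames(adj)], rowSums(adj))
})

test_that("edge profiles classify band pairs and summarize in percent", {
  # all nodes high prevalence: single class, zero differences
  uni <- toy_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                weight = 1, joint_prevalence = 0.05),
                     prevalence = c(a = 0.10, b = 0.10, c = 0.10))
  prof <- edge_profile(uni)
  expect_equal(unname(prof$band_pair_percentages["high-high"]), 100)
  expect_equal(sum(prof$band_pair_percentages), 100)
  expect_equal(unname(prof$prevalence_difference_summary),
               c(0, 0, 0), ignore_attr = TRUE)
  # single low-high edge: 100% high-low, difference 7.5%
  lh <- toy_network(data.frame(from = "rare", to = "common", weight = 1,
                               joint_prevalence = 0.004),
                    prevalence = c(rare = 0.005, common = 0.08))
  prof <- edge_profile(lh)
  expect_equal(unname(prof$band_pair_percentages["high-low"]), 100)
  expect_equal(unname(prof$prevalence_difference_summary["median"]), 7.5)
  # four edges, one per class -> 25% each (direct recount)
  prev <- c(l1 = 0.004, l2 = 0.006, m1 = 0.03, m2 = 0.05, h1 = 0.1, h2 = 0.2)
  quad <- toy_network(data.frame(from = c("l1", "l2", "m1", "h1"),
                                 to = c("l2", "m1", "m2", "h2"),
                                 weight = 1, joint_prevalence = 0.002),
                      prevalence = prev)
  prof <- edge_profile(quad)
  expect_equal(unname(prof$band_pair_percentages[c("low-low", "moderate-low",
                                                   "moderate-moderate",
                                                   "high-high")]),
               rep(25, 4))
  expect_true(prof$joint_prevalence_summary["q1"] <=
                prof$joint_prevalence_summary["median"])
  expect_true(prof$joint_prevalence_summary["median"] <=
                prof$joint_prevalence_summary["q3"])
})

test_that("band boundaries are closed on the left of each upper band", {
  b <- prevalence_band(c(0.0099, 0.01, 0.0699, 0.07))
  expect_equal(as.character(b), c("low", "moderate", "moderate", "high"))
})

test_that("network exports round-trip (GraphML) and are well formed (GEXF)", {
  ta <- make_test_assoc(seed = 5)
  net <- build_network(ta$assoc, "phi", "top_k", k = 10,
                       prevalence = ta$cohort$prevalence)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net$graph))
  expect_setequal(igraph::V(back)$name, igraph::V(net$graph)$name)
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(net$graph)$weight))

  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_gexf(net, gexf)
  lines <- readLines(gexf)
  expect_equal(sum(grepl("<node id=", lines)), igraph::vcount(net$graph))
  expect_equal(sum(grepl("<edge id=", lines)), igraph::ecount(net$graph))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_edgelist_csv(net, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), igraph::ecount(net$graph))
})
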