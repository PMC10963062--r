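# Co-abundance network construction, communities, centralities, and
# cross-network comparison.

# Build a network object directly from an edge list, for topology tests.
net_from_edges <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (nrow(edges)) igraph::E(g)$weight <- edges$weight
  structure(list(group = NULL,
                 nodes = data.frame(feature = nodes, mean_abundance = 1),
                 edges = data.frame(source = edges$source,
                                    target = edges$target,
                                    rho = edges$weight,
                                    p = rep(0, nrow(edges)),
                                    q = rep(0, nrow(edges)),
                                    sign = rep("positive", nrow(edges))),
                 graph = g),
            class = "coabundance_network")
}

clique_pair <- function() {
  # two 4-cliques joined by a single bridge edge
  e <- rbind(t(utils::combn(paste0("a", 1:4), 2)),
             t(utils::combn(paste0("b", 1:4), 2)),
             c("a1", "b1"))
  net_from_edges(c(paste0("a", 1:4), paste0("b", 1:4)),
                 data.frame(source = e[, 1], target = e[, 2], weight = 1,
                            stringsAsFactors = FALSE))
}

test_that("perfectly monotone features are connected with rho = 1", {
  set.seed(8)
  x <- sort(rexp(12)) + 1
  v <- rbind(f1 = x, f2 = x^2, f3 = rexp(12) + 1, f4 = rexp(12) + 1,
             f5 = rexp(12) + 1)
  colnames(v) <- paste0("s", 1:12)
  ft <- feature_table(v, units = "counts")
  net <- build_coabundance(ft, paste0("s", 1:12), top_n = 5)
  hit <- net$edges[(net$edges$source == "f1" & net$edges$target == "f2") |
                     (net$edges$source == "f2" & net$edges$target == "f1"), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$rho, 1)
})

test_that("node selection takes top_n by mean abundance with name tie-break", {
  v <- matrix(rep(c(10, 10, 5, 4, 3, 2, 1, 1, 1, 1), 6), 10, 6)
  rownames(v) <- c("zeta", "alpha", paste0("f", 3:10))
  colnames(v) <- paste0("s", 1:6)
  v <- v + matrix(runif(60, 0, 1e-6), 10, 6)  # avoid constant features
  v["zeta", ] <- v["alpha", ] <- c(10, 11, 12, 9, 10, 11)
  ft <- feature_table(v, units = "counts")
  net <- suppressWarnings(build_coabundance(ft, paste0("s", 1:6), top_n = 5,
                                            min_abs_rho = 0.99, alpha = 1e-9))
  expect_equal(nrow(net$nodes), 5)
  # tied means resolved alphabetically: alpha before zeta
  expect_equal(net$nodes$feature[1:2], c("alpha", "zeta"))
  expect_error(build_coabundance(ft, paste0("s", 1:6), top_n = 50), "top_n")
  expect_error(build_coabundance(ft, paste0("s", 1:3), top_n = 5), ">= 5")
})

test_that("greedy modularity separates two bridged cliques and merges a complete graph", {
  comm <- detect_communities(clique_pair())
  expect_equal(length(unique(comm)), 2)
  expect_equal(length(unique(comm[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(comm[paste0("b", 1:4)])), 1)
  # the 2-block split found is the best of all 2-partitions (brute force)
  g <- clique_pair()$graph
  best <- -Inf
  for (mask in 1:(2^7 - 1)) {  # fix node 8's side; enumerate the rest
    memb <- c(as.integer(intToBits(mask))[1:7], 0L) + 1L
    best <- max(best, igraph::modularity(g, memb))
  }
  expect_gte(igraph::modularity(g, comm), best - 1e-12)

  full <- net_from_edges(paste0("n", 1:5), {
    e <- t(utils::combn(paste0("n", 1:5), 2))
    data.frame(source = e[, 1], target = e[, 2], weight = 1,
               stringsAsFactors = FALSE)
  })
  expect_equal(length(unique(detect_communities(full))), 1)

  lonely <- net_from_edges(paste0("n", 1:4),
                           data.frame(source = character(),
                                      target = character(),
                                      weight = numeric()))
  expect_warning(comm2 <- detect_communities(lonely), "edgeless")
  expect_equal(length(unique(comm2)), 4)
})

test_that("centralities match hand-enumerated values on canonical graphs", {
  # complete K5: degree 4 everywhere, eigenvector entries all equal
  e <- t(utils::combn(paste0("n", 1:5), 2))
  k5 <- net_from_edges(paste0("n", 1:5),
                       data.frame(source = e[, 1], target = e[, 2],
                                  weight = 1, stringsAsFactors = FALSE))
  p5 <- node_properties(k5)
  expect_equal(p5$degree, rep(4, 5))
  expect_equal(p5$eigenvector, rep(1 / sqrt(5), 5))
  expect_equal(p5$closeness, rep(1, 5))

  # path A-B-C: B carries the single shortest path, ends carry none
  path <- net_from_edges(c("A", "B", "C"),
                         data.frame(source = c("A", "B"),
                                    target = c("B", "C"), weight = 1,
                                    stringsAsFactors = FALSE))
  pp <- node_properties(path)
  expect_equal(pp$betweenness[pp$feature == "B"], 1)
  expect_equal(pp$betweenness[pp$feature != "B"], c(0, 0))
  expect_equal(pp$closeness[pp$feature == "B"], 1)
  expect_equal(pp$closeness[pp$feature == "A"], 2 / 3)

  # star: the hub has strictly maximal closeness
  star <- net_from_edges(c("hub", paste0("leaf", 1:4)),
                         data.frame(source = "hub",
                                    target = paste0("leaf", 1:4), weight = 1,
                                    stringsAsFactors = FALSE))
  ps <- node_properties(star)
  hub <- ps$closeness[ps$feature == "hub"]
  expect_true(all(hub > ps$closeness[ps$feature != "hub"]))

  # eigenvector centrality is invariant to uniform weight scaling
  scaled <- k5
  igraph::E(scaled$graph)$weight <- 7 * igraph::E(scaled$graph)$weight
  expect_equal(node_properties(scaled)$eigenvector, p5$eigenvector)
})

test_that("topology comparison flags constant properties and detects density shifts", {
  e <- t(utils::combn(paste0("n", 1:6), 2))
  k6 <- net_from_edges(paste0("n", 1:6),
                       data.frame(source = e[, 1], target = e[, 2],
                                  weight = 1, stringsAsFactors = FALSE))
  empty6 <- net_from_edges(paste0("m", 1:6),
                           data.frame(source = character(),
                                      target = character(),
                                      weight = numeric()))
  cmp <- compare_properties(k6, empty6)
  expect_lt(cmp$p[cmp$property == "degree"], 0.01)
  # identical networks: every property compares at p = 1
  cmp_same <- compare_properties(k6, k6)
  expect_equal(cmp_same$p, rep(1, 4))
  expect_true(all(cmp_same$constant | cmp_same$p == 1))
})

test_that("dense and sparse random networks separate on degree", {
  set.seed(14)
  rand_net <- function(p_edge, nodes) {
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p_edge
    net_from_edges(nodes, data.frame(source = pairs[keep, 1],
                                     target = pairs[keep, 2],
                                     weight = 1, stringsAsFactors = FALSE))
  }
  hits <- 0
  for (i in 1:20) {
    a <- rand_net(0.6, paste0("a", 1:30))
    b <- rand_net(0.1, paste0("b", 1:30))
    p <- compare_properties(a, b)
    hits <- hits + (p$p[p$property == "degree"] < 0.05)
  }
  expect_gte(hits, 19)
})
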