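# Per-group co-abundance networks: Spearman correlation edges among the
# most abundant taxa, greedy-modularity communities, node centralities,
# and cross-group topology comparison.

#' Build a co-abundance network for one sample group
#'
#' Nodes are the `top_n` features with the highest mean relative abundance
#' within the group (ties broken by feature name); edges connect pairs
#' whose Spearman correlation (average ranks for ties) satisfies
#' `|rho| >= min_abs_rho` with BH-adjusted correlation-test q below
#' `alpha`. Negative correlations are kept as edges with a sign attribute.
#'
#' @param ft A `feature_table` (relative abundances recommended).
#' @param group_samples Sample ids of the group (>= 5).
#' @param top_n Number of most-abundant features to use as nodes
#'   (default 30).
#' @param min_abs_rho Minimum absolute Spearman correlation (default 0.3).
#' @param alpha BH-q threshold for edge inclusion (default 0.05).
#' @param group Optional group label stored on the network.
#' @return A `coabundance_network`: list with `group`, `nodes` (data frame
#'   of feature and mean abundance), `edges` (source, target, rho, p, q,
#'   sign), and the `igraph` graph.
#' @export
build_coabundance <- function(ft, group_samples, top_n = 30,
                              min_abs_rho = 0.3, alpha = 0.05,
                              group = NULL) {
  if (length(group_samples) < 5) {
    stop("need >= 5 samples in the group for correlation edges", call. = FALSE)
  }
  sub <- subset_samples(ft, group_samples)
  means <- rowMeans(sub$values)
  if (top_n > length(means)) {
    stop("top_n (", top_n, ") exceeds feature count (", length(means), ")",
         call. = FALSE)
  }
  ord <- order(-means, names(means))
  nodes <- names(means)[ord][seq_len(top_n)]
  if (length(nodes) < 2) stop("fewer than 2 nodes selected", call. = FALSE)
  v <- t(sub$values[nodes, , drop = FALSE])  # samples x nodes

  pairs <- utils::combn(nodes, 2)
  rho <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ct <- suppressWarnings(
      stats::cor.test(v[, pairs[1, k]], v[, pairs[2, k]],
                      method = "spearman", exact = FALSE))
    rho[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  q <- bh_adjust(p)
  keep <- abs(rho) >= min_abs_rho & q < alpha & !is.na(rho)
  edges <- data.frame(source = pairs[1, keep], target = pairs[2, keep],
                      rho = rho[keep], p = p[keep], q = q[keep],
                      sign = ifelse(rho[keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  if (nrow(edges)) igraph::E(g)$weight <- abs(edges$rho)

  structure(list(group = group,
                 nodes = data.frame(feature = nodes,
                                    mean_abundance = unname(means[nodes]),
                                    stringsAsFactors = FALSE),
                 edges = edges, graph = g),
            class = "coabundance_network")
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat(sprintf("<coabundance_network>%s %d nodes, %d edges\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Detect communities by greedy modularity maximization
#'
#' Greedy agglomerative modularity optimization on absolute edge weights
#' (deterministic under a fixed node ordering). Isolated nodes form
#' singleton communities; an edgeless network yields all singletons with a
#' warning.
#'
#' @param net A `coabundance_network`.
#' @return Named integer vector of community ids covering every node.
#' @export
detect_communities <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0) {
    warning("edgeless network: every node is its own community", call. = FALSE)
    return(stats::setNames(seq_len(igraph::vcount(g)),
                           igraph::V(g)$name))
  }
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(comm)
  # the dendrogram cut can score below the trivial one-community partition
  # (modularity 0); never return a worse-than-trivial split
  if (igraph::modularity(g, memb, weights = igraph::E(g)$weight) < 0) {
    memb <- rep(1L, igraph::vcount(g))
  }
  stats::setNames(memb, igraph::V(g)$name)
}

#' Node-level topological properties
#'
#' Degree (edge count), closeness `(n_c - 1) / sum of shortest-path
#' lengths` within the node's connected component of size `n_c` (0 for
#' isolated nodes; `harmonic = TRUE` gives the harmonic mean alternative
#' averaged over all other nodes), normalized shortest-path betweenness,
#' and eigenvector centrality (principal eigenvector of the
#' absolute-weight adjacency matrix, L2-normalized and non-negative).
#' Path-based measures treat edges as unit length.
#'
#' @param net A `coabundance_network`.
#' @param harmonic Use harmonic closeness instead (default `FALSE`).
#' @return Data frame with `feature`, `degree`, `closeness`,
#'   `betweenness`, `eigenvector`.
#' @export
node_properties <- function(net, harmonic = FALSE) {
  g <- net$graph
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  d <- igraph::distances(g, weights = NA)   # unit-length shortest paths

  clo <- vapply(seq_len(n), function(i) {
    finite <- is.finite(d[i, ]) & seq_len(n) != i
    if (!any(finite)) return(0)
    if (harmonic) {
      sum(1 / d[i, finite]) / (n - 1)
    } else {
      sum(finite) / sum(d[i, finite])
    }
  }, numeric(1))

  btw <- if (n > 2) {
    igraph::betweenness(g, weights = NA, normalized = TRUE)
  } else {
    stats::setNames(numeric(n), igraph::V(g)$name)
  }

  if (igraph::ecount(g) == 0) {
    eig <- numeric(n)
  } else {
    adj <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    es <- eigen(adj, symmetric = TRUE)
    v1 <- es$vectors[, 1]
    if (sum(v1) < 0) v1 <- -v1
    eig <- abs(v1) / sqrt(sum(v1^2))
  }

  data.frame(feature = igraph::V(g)$name, degree = unname(deg),
             closeness = clo, betweenness = unname(btw),
             eigenvector = eig, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare topological properties of two networks
#'
#' Two-sided Wilcoxon rank-sum tests on the per-node distributions of
#' degree, closeness, betweenness, and eigenvector centrality. A property
#' constant (and equal) in both networks is reported with p = 1 and
#' flagged.
#'
#' @param net_a,net_b `coabundance_network` objects.
#' @return Data frame with `property`, `p`, `constant`.
#' @export
compare_properties <- function(net_a, net_b) {
  pa <- node_properties(net_a)
  pb <- node_properties(net_b)
  props <- c("degree", "closeness", "betweenness", "eigenvector")
  res <- lapply(props, function(pr) {
    a <- pa[[pr]]; b <- pb[[pr]]
    if (max(c(a, b)) == min(c(a, b))) {
      return(data.frame(property = pr, p = 1, constant = TRUE,
                        stringsAsFactors = FALSE))
    }
    data.frame(property = pr, p = wilcoxon_rank_sum(a, b)$p,
               constant = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cross-comparison network-degree matrix
#'
#' Builds co-abundance networks independently for the case and control
#' group of each comparison and assembles a features x (comparison, group)
#' matrix of node degrees for heatmap export. No information is shared
#' across comparisons.
#'
#' @param tables List of `feature_table`s, one per comparison.
#' @param metas List of aligned metadata, one per comparison.
#' @param designs Comparison design data frame.
#' @param top_n,min_abs_rho,alpha Passed to [build_coabundance()].
#' @return Numeric matrix of degrees (NA where a feature is not a node in
#'   that network).
#' @export
network_degree_matrix <- function(tables, metas, designs, top_n = 30,
                                  min_abs_rho = 0.3, alpha = 0.05) {
  cols <- list()
  for (i in seq_len(nrow(designs))) {
    des <- designs[i, ]
    for (side in c("case", "control")) {
      grp <- if (side == "case") des$case_group else des$control_group
      ids <- metas[[i]]$sample_id[metas[[i]]$group == grp]
      net <- build_coabundance(tables[[i]], ids,
                               top_n = min(top_n, nrow(tables[[i]]$values)),
                               min_abs_rho = min_abs_rho, alpha = alpha,
                               group = grp)
      props <- node_properties(net)
      cols[[paste(des$comparison_id, side, sep = ".")]] <-
        stats::setNames(props$degree, props$feature)
    }
  }
  feats <- sort(unique(unlist(lapply(cols, names))))
  mat <- matrix(NA_real_, length(feats), length(cols),
                dimnames = list(feats, names(cols)))
  for (nm in names(cols)) mat[names(cols[[nm]]), nm] <- cols[[nm]]
  mat
}
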