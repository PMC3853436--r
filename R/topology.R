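## Network topology: per-node centralities and the whole-network summary
## statistics reported for both interaction networks, plus the sequential
## top-degree removal experiment. Edges are treated as unweighted for all
## path-based quantities (MI weights rank edges, not distances).

#' Per-node centralities of an interaction network
#'
#' Degree (incident edges), unnormalised shortest-path betweenness with
#' fractional credit over equally short paths, closeness normalised within
#' each node's connected component (`(n_c - 1) / sum of geodesics`; isolated
#' nodes get 0), and the local clustering coefficient (0 for degree < 2).
#'
#' @param network an `mi_network` or any undirected igraph object.
#' @return data.frame (node, degree, betweenness, closeness, clustering) in
#'   vertex order.
#' @export
node_centralities <- function(network) {
  n <- igraph::vcount(network)
  if (n < 1) stop_input("network has no nodes")
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE, weights = NA,
                             normalized = FALSE)
  clu <- igraph::transitivity(network, type = "local", isolates = "zero",
                              weights = NA)
  comp <- igraph::components(network)$membership
  d <- igraph::distances(network, weights = NA)
  clo <- vapply(seq_len(n), function(v) {
    in_comp <- comp == comp[v]
    nc <- sum(in_comp)
    if (nc < 2) return(0)
    (nc - 1) / sum(d[v, in_comp & seq_len(n) != v])
  }, numeric(1))
  data.frame(node = igraph::V(network)$name, degree = as.numeric(deg),
             betweenness = as.numeric(btw), closeness = clo,
             clustering = as.numeric(clu),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Whole-network topology summary
#'
#' The summary statistics used to compare the two interaction networks:
#' edge count, averaged centralities, density `2E / (n(n-1))`, degree
#' heterogeneity `sd(degree) / mean(degree)`, Freeman degree centralization
#' `sum(max_deg - deg) / ((n-1)(n-2))`, characteristic path length (mean
#' geodesic over connected ordered pairs), and the diameter and radius of the
#' largest connected component.
#'
#' @inheritParams node_centralities
#' @return a one-row data.frame with columns n_nodes, n_edges, avg_degree,
#'   avg_betweenness, avg_clustering, avg_closeness, density, heterogeneity,
#'   centralization, char_path_length, diameter, radius.
#' @export
network_summary <- function(network) {
  cent <- node_centralities(network)
  n <- nrow(cent)
  deg <- cent$degree
  density <- if (n > 1) 2 * igraph::ecount(network) / (n * (n - 1)) else 0
  heterogeneity <- if (mean(deg) > 0) stats::sd(deg) / mean(deg) else 0
  if (n < 3) {
    warning("fewer than 3 nodes: centralization reported as 0", call. = FALSE)
    centralization <- 0
  } else {
    centralization <- sum(max(deg) - deg) / ((n - 1) * (n - 2))
  }
  d <- igraph::distances(network, weights = NA)
  finite <- is.finite(d) & upper.tri(d)
  cpl <- if (any(finite)) mean(d[finite]) else NA_real_
  comp <- igraph::components(network)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(network, which(comp$membership == big))
  if (igraph::vcount(sub) > 1) {
    ecc <- igraph::eccentricity(sub)
    diameter <- max(ecc); radius <- min(ecc)
  } else {
    diameter <- 0; radius <- 0
  }
  data.frame(n_nodes = n, n_edges = igraph::ecount(network),
             avg_degree = mean(deg), avg_betweenness = mean(cent$betweenness),
             avg_clustering = mean(cent$clustering),
             avg_closeness = mean(cent$closeness), density = density,
             heterogeneity = heterogeneity, centralization = centralization,
             char_path_length = cpl, diameter = as.numeric(diameter),
             radius = as.numeric(radius), row.names = NULL)
}

#' Sequential top-degree node removal experiment
#'
#' Ranks nodes by degree on the intact network (ties broken by lexicographic
#' ID), removes the top `top_n` one at a time, and records the average degree
#' and characteristic path length of the remaining graph after each removal.
#'
#' @inheritParams node_centralities
#' @param top_n number of top-ranked nodes to remove (must be < node count).
#' @return data.frame with `top_n + 1` rows (removed_count starting at 0,
#'   removed_node, avg_degree, char_path_length).
#' @export
removal_curve <- function(network, top_n = 10) {
  n <- igraph::vcount(network)
  if (!is.numeric(top_n) || top_n < 1 || top_n >= n)
    stop_input("'top_n' must be in [1, n_nodes - 1]")
  top_n <- as.integer(top_n)
  deg <- igraph::degree(network)
  ids <- igraph::V(network)$name
  ranked <- ids[order(-deg, ids)][seq_len(top_n)]
  step_stats <- function(g) {
    dd <- igraph::distances(g, weights = NA)
    finite <- is.finite(dd) & upper.tri(dd)
    c(avg_degree = mean(igraph::degree(g)),
      char_path_length = if (any(finite)) mean(dd[finite]) else NA_real_)
  }
  out <- matrix(NA_real_, top_n + 1, 2)
  g <- network
  out[1, ] <- step_stats(g)
  for (i in seq_len(top_n)) {
    g <- igraph::delete_vertices(g, ranked[i])
    out[i + 1, ] <- step_stats(g)
  }
  data.frame(removed_count = 0:top_n, removed_node = c(NA, ranked),
             avg_degree = out[, 1], char_path_length = out[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}
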