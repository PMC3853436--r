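# Independent brute-force oracles used to validate the package's graph,
# PCA, Poisson and log-rank computations on small instances. These are
# written from first principles (adjacency matrices, explicit path
# enumeration, pmf summation) and share no code with the implementation.

# all-pairs shortest-path distances by BFS on an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(d[s, w]) && w != s) {
            d[s, w] <- depth
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# enumerate every shortest s->t path (as vertex sequences)
oracle_all_shortest_paths <- function(adj, d, s, t) {
  if (is.infinite(d[s, t])) return(list())
  if (s == t) return(list(s))
  paths <- list()
  extend <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] == 1)) {
      if (d[s, w] == d[s, v] + 1 && d[w, t] == d[s, t] - d[s, w])
        extend(c(path, w))
    }
  }
  extend(s)
  paths
}

# degree, fractional betweenness (each unordered pair counted once),
# per-component normalized closeness, local clustering coefficient
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  deg <- rowSums(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(d[s, t])) next
      paths <- oracle_all_shortest_paths(adj, d, s, t)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(paths)
      }
    }
  }
  clo <- numeric(n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(d[v, ]))
    if (length(comp) < 2) next
    clo[v] <- (length(comp) - 1) / sum(d[v, setdiff(comp, v)])
  }
  clu <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb]) / 2
    clu[v] <- 2 * links / (k * (k - 1))
  }
  list(degree = unname(deg), betweenness = btw, closeness = clo,
       clustering = clu, distances = d)
}

oracle_summary <- function(adj) {
  n <- nrow(adj)
  cent <- oracle_centralities(adj)
  d <- cent$distances
  n_edges <- sum(adj) / 2
  deg <- cent$degree
  finite <- is.finite(d) & upper.tri(d)
  comp_of <- function(v) which(is.finite(d[v, ]))
  sizes <- vapply(seq_len(n), function(v) length(comp_of(v)), integer(1))
  big <- comp_of(which.max(sizes))
  ecc <- vapply(big, function(v) max(d[v, big]), numeric(1))
  list(n_edges = n_edges, avg_degree = mean(deg),
       avg_betweenness = mean(cent$betweenness),
       avg_clustering = mean(cent$clustering),
       avg_closeness = mean(cent$closeness),
       density = n_edges / (n * (n - 1) / 2),
       heterogeneity = if (mean(deg) > 0) sd(deg) / mean(deg) else 0,
       centralization = sum(max(deg) - deg) / ((n - 1) * (n - 2)),
       char_path_length = if (any(finite)) mean(d[finite]) else NA_real_,
       diameter = if (length(big) > 1) max(ecc) else 0,
       radius = if (length(big) > 1) min(ecc) else 0)
}

# exhaustive-triple DPI: returns logical keep matrix
oracle_dpi <- function(mi, eps) {
  p <- nrow(mi)
  keep <- matrix(TRUE, p, p)
  if (p < 3) return(keep)
  for (i in 1:(p - 2)) for (j in (i + 1):(p - 1)) for (k in (j + 1):p) {
    if (mi[i, j] < mi[j, k] - eps && mi[i, j] < mi[i, k] - eps) {
      keep[i, j] <- keep[j, i] <- FALSE
    }
    if (mi[j, k] < mi[i, j] - eps && mi[j, k] < mi[i, k] - eps) {
      keep[j, k] <- keep[k, j] <- FALSE
    }
    if (mi[i, k] < mi[i, j] - eps && mi[i, k] < mi[j, k] - eps) {
      keep[i, k] <- keep[k, i] <- FALSE
    }
  }
  keep
}

# Poisson upper tail by direct pmf summation (exp/lgamma form)
oracle_poisson_tail <- function(lam, t) {
  ks <- t:(t + 500)
  sum(exp(-lam + ks * log(lam) - lgamma(ks + 1)))
}

# first PC of a genes x samples block via eigendecomposition of the
# gene-gene covariance; returns |score| comparison material
oracle_first_pc <- function(X) {
  Xc <- X - rowMeans(X)
  S <- Xc %*% t(Xc)
  e <- eigen(S, symmetric = TRUE)
  w1 <- e$vectors[, 1]
  score <- as.numeric(t(Xc) %*% w1)
  list(score = score, var_explained = e$values[1] / sum(pmax(e$values, 0)))
}

# two-group log-rank chi-square from the observed/expected table
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  o1 <- e1 <- v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    dth <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + dth * n1 / n
    if (n > 1)
      v <- v + dth * (n1 / n) * (1 - n1 / n) * (n - dth) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# random undirected graph as adjacency matrix + the matching igraph object
random_graph_pair <- function(n, p_edge) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1
  }
  ids <- sprintf("N%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(adj = adj, graph = g, ids = ids)
}

# small labelled expression matrix for classifier/diffexpr tests
toy_matrix <- function(n_feat = 6, n_a = 8, n_b = 12, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * (n_a + n_b)), n_feat,
              dimnames = list(sprintf("f%02d", 1:n_feat),
                              sprintf("s%02d", 1:(n_a + n_b))))
  lab <- setNames(rep(c("basal_like", "luminal_A"), c(n_a, n_b)), colnames(m))
  attr(m, "labels") <- lab
  m
}
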