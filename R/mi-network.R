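## Mutual-information network inference: KSG (Kraskov-Stoegbauer-Grassberger)
## algorithm-1 kNN estimator over all feature pairs, then ARACNE-style
## data-processing-inequality pruning of dominated (indirect) edges.

#' KSG k-nearest-neighbour mutual information estimate
#'
#' Algorithm-1 estimator in nats: `psi(k) + psi(N) - mean_i[psi(n_x(i) + 1) +
#' psi(n_y(i) + 1)]`, with the Chebyshev (max) norm in the joint space and
#' strict-inequality marginal counts inside each point's k-th neighbour
#' distance. A deterministic uniform jitter of amplitude 1e-10, shared by the
#' two coordinates, breaks ties before the neighbour search (the derivation
#' assumes continuous marginals); the estimate is exactly symmetric in
#' `(x, y)` and reproducible given `jitter_seed`. Negative estimates are
#' clamped to 0.
#'
#' @param x,y numeric vectors of equal length `>= k_neighbors + 2`.
#' @param k_neighbors neighbour count `k` (default 3).
#' @param jitter_seed seed of the tie-breaking jitter stream.
#' @return MI estimate in nats (>= 0). A constant input vector returns 0 with
#'   a warning (MI with a degenerate variable is 0 by convention).
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(500)
#' ksg_mutual_information(x, y)          # near -0.5 * log(1 - 0.81) = 0.830
#' @export
ksg_mutual_information <- function(x, y, k_neighbors = 3, jitter_seed = 0L) {
  if (length(x) != length(y))
    stop_input("'x' and 'y' have different lengths (%d vs %d)",
               length(x), length(y))
  k <- as.integer(k_neighbors)
  if (is.na(k) || k < 1) stop_input("'k_neighbors' must be a positive integer")
  if (length(x) < k + 2)
    stop_input("need at least k_neighbors + 2 = %d observations, got %d",
               k + 2, length(x))
  if (anyNA(x) || anyNA(y)) stop_input("'x' and 'y' must not contain NA")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input vector: returning MI = 0", call. = FALSE)
    return(0)
  }
  ksg_mi_cpp(as.numeric(x), as.numeric(y), k, 1e-10, as.integer(jitter_seed))
}

#' All-pairs mutual information matrix
#'
#' @param values numeric feature-by-sample matrix.
#' @inheritParams ksg_mutual_information
#' @return symmetric matrix of pairwise KSG estimates with `NA` diagonal;
#'   rows/columns named by feature. Constant feature rows contribute 0 to
#'   every pair (with a warning). A matrix with fewer than 2 features yields
#'   no pairs.
#' @export
pairwise_mi <- function(values, k_neighbors = 3, jitter_seed = 0L) {
  k <- as.integer(k_neighbors)
  p <- nrow(values)
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("F%d", seq_len(p))
  if (p < 2) {
    m <- matrix(NA_real_, p, p, dimnames = list(ids, ids))
    return(m)
  }
  if (ncol(values) < k + 2)
    stop_input("need at least k_neighbors + 2 = %d samples, got %d",
               k + 2, ncol(values))
  mi <- ksg_mi_matrix_cpp(values, k, 1e-10, as.integer(jitter_seed))
  dimnames(mi) <- list(ids, ids)
  const <- apply(values, 1, function(r) stats::var(r) == 0)
  if (any(const)) {
    warning(sprintf("%d constant feature row(s): their MI set to 0",
                    sum(const)), call. = FALSE)
    mi[const, ] <- 0
    mi[, const] <- 0
    diag(mi) <- NA_real_
  }
  mi
}

#' Prune indirect edges with the data-processing inequality
#'
#' Starting from the complete graph weighted by the MI matrix, every
#' unordered triple `{i, j, k}` marks edge `(i, j)` for removal when
#' `MI(i;j) < MI(j;k) - epsilon` and `MI(i;j) < MI(i;k) - epsilon`. All
#' triples are evaluated against the original matrix and marked edges are
#' removed simultaneously, so the result does not depend on any processing
#' order. Edges with non-positive MI are not retained.
#'
#' @param mi_matrix square symmetric matrix of pairwise MI (diagonal
#'   ignored).
#' @param epsilon DPI tolerance (>= 0; default 0.05 nats).
#' @return an `mi_network`: an undirected igraph over all features (isolated
#'   nodes kept) whose edges carry the `mi` weight; the estimator parameters
#'   are stored as graph attributes.
#' @export
dpi_prune <- function(mi_matrix, epsilon = 0.05) {
  if (!is.matrix(mi_matrix) || nrow(mi_matrix) != ncol(mi_matrix))
    stop_input("'mi_matrix' must be a square matrix")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || is.na(epsilon) ||
      epsilon < 0)
    stop_input("'epsilon' must be a single number >= 0")
  p <- nrow(mi_matrix)
  ids <- rownames(mi_matrix)
  if (is.null(ids)) ids <- sprintf("F%d", seq_len(p))
  off <- mi_matrix
  diag(off) <- 0
  if (p >= 2 && any(abs(off - t(off)) > 1e-9, na.rm = TRUE))
    stop_input("'mi_matrix' must be symmetric")
  if (p < 2)
    return(new_mi_network(data.frame(node_a = character(0),
                                     node_b = character(0),
                                     mi_nats = numeric(0)),
                          ids, NA_integer_, epsilon))
  keep <- if (p >= 3) dpi_keep_cpp(mi_matrix, epsilon) else
    matrix(TRUE, p, p)
  iu <- which(upper.tri(mi_matrix) & keep & mi_matrix > 0, arr.ind = TRUE)
  edges <- data.frame(node_a = ids[iu[, 1]], node_b = ids[iu[, 2]],
                      mi_nats = mi_matrix[iu], stringsAsFactors = FALSE)
  new_mi_network(edges, ids, NA_integer_, epsilon)
}

#' Permutation-null mutual information floor
#'
#' Largest KSG estimate observed over `n_null` feature pairs whose sample
#' order has been permuted in one member -- an empirical null for "no
#' dependence at this sample size". MI values at or below this floor are
#' indistinguishable from estimator noise: kNN MI estimates of independent
#' pairs are not 0 but scatter with spread of order `1/sqrt(n)`, and the DPI
#' rule alone cannot remove such edges (two independent features rarely share
#' one neighbour dominating both ends by `epsilon`), so without a floor they
#' accumulate into a dense background that buries the degree signal.
#'
#' @inheritParams pairwise_mi
#' @param n_null number of permuted pairs to draw (default 1000).
#' @param seed RNG seed for pair selection and permutation.
#' @return the floor (max null MI, in nats).
#' @export
mi_null_floor <- function(values, k_neighbors = 3, n_null = 1000,
                          seed = 0L, jitter_seed = 0L) {
  p <- nrow(values)
  if (p < 2) return(0)
  with_seed(seed, {
    null_mi <- vapply(seq_len(n_null), function(b) {
      ij <- sample.int(p, 2)
      ksg_mi_cpp(values[ij[1], ], values[ij[2], sample.int(ncol(values))],
                 as.integer(k_neighbors), 1e-10, as.integer(jitter_seed))
    }, numeric(1))
    max(null_mi)
  })
}

#' Build a miRNA interaction network from an expression matrix
#'
#' [pairwise_mi()] over all feature pairs, an MI significance floor, then
#' [dpi_prune()]. By default the floor is the permutation null maximum from
#' [mi_null_floor()]: pairwise MI at or below it is zeroed before the DPI
#' step, so only dependencies exceeding anything produced by independent
#' features at this sample size enter the graph. `mi_floor = "none"` skips
#' the floor (DPI-only pruning of the complete graph); a number uses that
#' fixed floor in nats. All parameters are recorded on the returned network.
#'
#' @inheritParams pairwise_mi
#' @inheritParams dpi_prune
#' @param mi_floor `"null_max"` (default), `"none"`/`NULL`, or a numeric
#'   floor in nats.
#' @param n_null permuted pairs used by the `"null_max"` floor.
#' @return an `mi_network` igraph object.
#' @examples
#' sim <- generate_dual_dataset(synthetic_config(n_mirna = 20, n_hubs = 2,
#'                                               n_genes = 80, seed = 11))
#' net <- build_network(sim$mirna)
#' igraph::ecount(net)
#' @export
build_network <- function(values, k_neighbors = 3, epsilon = 0.05,
                          mi_floor = "null_max", n_null = 1000,
                          jitter_seed = 0L) {
  mi <- pairwise_mi(values, k_neighbors = k_neighbors,
                    jitter_seed = jitter_seed)
  if (is.null(mi_floor)) mi_floor <- "none"
  floor_value <- if (is.numeric(mi_floor)) {
    mi_floor
  } else if (identical(mi_floor, "null_max")) {
    mi_null_floor(values, k_neighbors = k_neighbors, n_null = n_null,
                  seed = jitter_seed, jitter_seed = jitter_seed)
  } else if (identical(mi_floor, "none")) {
    0
  } else {
    stop_input("'mi_floor' must be \"null_max\", \"none\" or a number")
  }
  if (floor_value > 0) mi[mi <= floor_value] <- 0
  g <- dpi_prune(mi, epsilon = epsilon)
  g$k_neighbors <- as.integer(k_neighbors)
  g$mi_floor <- floor_value
  g
}
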