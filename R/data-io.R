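## File formats. Everything is tab-separated UTF-8 with '.' decimals:
## expression matrices (first column feature IDs, header row sample IDs),
## a two-column sample->class sidecar, a two-column miRNA->gene target map,
## a survival table (sample_id, time, event), and network edge lists
## (node_a, node_b, mi_nats). Networks also round-trip through GraphML.

#' Read a feature-by-sample expression matrix from TSV
#'
#' The first column holds feature IDs and the header row sample IDs. Rows
#' containing any missing value are dropped with a warning giving the count.
#' Class labels may be supplied in a two-column sidecar TSV (sample, class).
#'
#' @param path path to the expression TSV.
#' @param labels_path optional path to the label sidecar TSV.
#' @return numeric matrix (features x samples); labels, when given, attached
#'   as the `labels` attribute (see [sample_labels()]).
#' @export
read_expression <- function(path, labels_path = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop_input("expression file '%s' has fewer than 2 sample columns", path)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop_input("duplicate feature ID(s) in '%s': %s", path,
               paste(utils::head(dup, 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    warning(sprintf("dropped %d feature row(s) with missing values from '%s'",
                    sum(bad), path), call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  if (!is.null(labels_path)) {
    lab <- read_labels(labels_path)
    missing <- setdiff(colnames(m), names(lab))
    if (length(missing) > 0)
      stop_input("label file '%s' is missing sample(s): %s", labels_path,
                 paste(utils::head(missing, 5), collapse = ", "))
    attr(m, "labels") <- lab[colnames(m)]
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric feature-by-sample matrix.
#' @param path output path.
#' @param feature_col header name of the feature-ID column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, feature_col = "feature_id") {
  df <- data.frame(rownames(mat), format_num(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(feature_col, colnames(mat))
  write_tsv(df, path)
}

#' @rdname read_expression
#' @export
read_labels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_input("label file '%s' needs 2 columns", path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_expression
#' @param labels named character vector (sample -> class).
#' @export
write_labels <- function(labels, path) {
  write_tsv(data.frame(sample_id = names(labels), class = unname(labels),
                       stringsAsFactors = FALSE), path)
}

#' Read a miRNA-to-target-gene map from a two-column TSV
#'
#' Columns are (mirna, gene), one pair per line, header row required. Blank
#' or missing IDs raise a format error naming the offending line.
#'
#' @param path path to the target-map TSV.
#' @return named list: miRNA ID -> character vector of distinct gene IDs.
#' @export
read_target_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop_input("target map '%s' needs 2 columns", path)
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]) |
                 trimws(df[[1]]) == "" | trimws(df[[2]]) == "")
  if (length(bad) > 0)  # +1 for the header line
    stop_input("target map '%s': blank miRNA or gene field at line %d",
               path, bad[1] + 1L)
  pairs <- split(df[[2]], df[[1]])
  lapply(pairs, function(g) sort(unique(g)))
}

#' @rdname read_target_map
#' @param targets named list mapping miRNA IDs to gene-ID vectors.
#' @export
write_target_map <- function(targets, path) {
  targets <- targets[lengths(targets) > 0]
  write_tsv(data.frame(mirna = rep(names(targets), lengths(targets)),
                       gene = unlist(targets, use.names = FALSE),
                       stringsAsFactors = FALSE), path)
}

#' Read or write a survival table (sample_id, time, event)
#'
#' @param path path to the survival TSV.
#' @return data.frame with columns sample_id (unique), time (>= 0), and
#'   event (0/1).
#' @export
read_survival <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "time", "event") %in% colnames(df)))
    stop_input("survival table '%s' needs columns sample_id, time, event", path)
  df <- df[, c("sample_id", "time", "event")]
  if (anyDuplicated(df$sample_id))
    stop_input("survival table '%s' has duplicate sample IDs", path)
  if (any(is.na(df$time)) || any(df$time < 0))
    stop_input("survival table '%s' has negative or missing times", path)
  if (!all(df$event %in% c(0L, 1L)))
    stop_input("survival table '%s': event must be 0 or 1", path)
  df
}

#' @rdname read_survival
#' @param survival data.frame with columns sample_id, time, event.
#' @export
write_survival <- function(survival, path) {
  survival$time <- format_num(survival$time)
  write_tsv(survival, path)
}

#' Write a mutual-information network as an edge-list TSV
#'
#' Columns (node_a, node_b, mi_nats); MI printed with 15 significant digits so
#' that read-write round trips are lossless to well below 1e-9. An empty
#' network yields a header-only file.
#'
#' @param network an `mi_network` (igraph object with an `mi` edge attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_edge_list()], [write_graphml()]
#' @export
write_edge_list <- function(network, path) {
  df <- network_edges(network)
  df$mi_nats <- format_num(df$mi_nats)
  write_tsv(df, path)
}

#' @rdname write_edge_list
#' @return for `read_edge_list`, an `mi_network` igraph object.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("node_a", "node_b", "mi_nats") %in% colnames(df)))
    stop_input("edge list '%s' needs columns node_a, node_b, mi_nats", path)
  nodes <- sort(unique(c(df$node_a, df$node_b)))
  new_mi_network(df, nodes, k_neighbors = NA_integer_, epsilon = NA_real_)
}

#' @rdname write_edge_list
#' @param centralities optional data.frame from [node_centralities()]; when
#'   supplied, degree/betweenness/closeness are written as GraphML node
#'   attributes.
#' @export
write_graphml <- function(network, path, centralities = NULL) {
  g <- network
  if (!is.null(centralities)) {
    idx <- match(igraph::V(g)$name, centralities$node)
    if (any(is.na(idx)))
      stop_input("centrality table does not cover all network nodes")
    igraph::V(g)$degree <- centralities$degree[idx]
    igraph::V(g)$betweenness <- centralities$betweenness[idx]
    igraph::V(g)$closeness <- centralities$closeness[idx]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

## ---- internal helpers -----------------------------------------------------

# 15 significant digits: round-trips well below 1e-9 relative error
format_num <- function(x) {
  out <- sprintf("%.15g", x)
  dim(out) <- dim(x)
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

# canonical sorted edge data.frame of an mi_network
network_edges <- function(network) {
  e <- igraph::as_data_frame(network, what = "edges")
  if (nrow(e) == 0)
    return(data.frame(node_a = character(0), node_b = character(0),
                      mi_nats = numeric(0), stringsAsFactors = FALSE))
  a <- pmin(e$from, e$to)
  b <- pmax(e$from, e$to)
  df <- data.frame(node_a = a, node_b = b, mi_nats = e$mi,
                   stringsAsFactors = FALSE)
  df[order(df$node_a, df$node_b), , drop = FALSE]
}

new_mi_network <- function(edges_df, nodes, k_neighbors, epsilon) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_df$node_a, to = edges_df$node_b,
               mi = edges_df$mi_nats, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  g$k_neighbors <- k_neighbors
  g$epsilon <- epsilon
  class(g) <- c("mi_network", class(g))
  g
}
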