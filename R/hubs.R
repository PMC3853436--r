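## Hub calling under a Poisson degree null and the common-hub report:
## the intersection of the two networks' hub sets with centralities averaged
## across networks, the pipeline's candidate miRNA list.

#' Poisson upper-tail probability for a node degree
#'
#' `P(X >= t)` for `X ~ Poisson(lam)` -- the chance a node reaches degree `t`
#' in a random network whose degrees follow a Poisson law with mean `lam`.
#' Computed through the complemented CDF for numerical stability.
#'
#' @param lam Poisson mean (> 0), conventionally the observed average degree.
#' @param t degree threshold (non-negative integer).
#' @return tail probability in `[0, 1]`.
#' @examples
#' poisson_degree_pvalue(14.06, 20)
#' @export
poisson_degree_pvalue <- function(lam, t) {
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam <= 0)
    stop_input("'lam' must be a single number > 0")
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0 || t != round(t))
    stop_input("'t' must be a non-negative integer")
  ppois(t - 1, lambda = lam, lower.tail = FALSE)
}

#' Call hubs by degree threshold
#'
#' @param centralities data.frame from [node_centralities()].
#' @param degree_threshold minimum degree for a hub (default 15).
#' @return character vector of hub node IDs.
#' @export
identify_hubs <- function(centralities, degree_threshold = 15) {
  centralities$node[centralities$degree >= degree_threshold]
}

#' Advisory hub threshold from the Poisson null
#'
#' Smallest degree `t` whose Poisson tail falls below `alpha` -- the degree
#' that would be a rare event in a random network with the observed average
#' degree. Advisory only; the operational hub rule stays at the relaxed
#' default threshold of [identify_hubs()].
#'
#' @param avg_degree observed average degree (Poisson mean of the null).
#' @param alpha rarity level (default 0.05); `alpha >= 1` returns 0.
#' @return integer threshold.
#' @export
suggest_threshold <- function(avg_degree, alpha = 0.05) {
  if (alpha >= 1) return(0L)
  t <- 0L
  while (poisson_degree_pvalue(avg_degree, t) >= alpha) t <- t + 1L
  t
}

#' Common-hub report across the two interaction networks
#'
#' Hubs are called in each network with the same degree threshold and
#' intersected; for each common hub the report averages degree, betweenness
#' and closeness over the two networks and carries the miRNA's subtype trend
#' label. Rows are sorted by average degree (descending), ties by average
#' betweenness (descending), then ID.
#'
#' @param cent_a,cent_b centrality tables of the two networks
#'   ([node_centralities()]); node sets may differ -- the intersection is
#'   taken on IDs.
#' @param trends optional named trend vector from [assign_trend()].
#' @param degree_threshold hub degree threshold applied to both networks.
#' @return a `hub_report`: list with `common_hubs` (data.frame: mirna,
#'   avg_degree, avg_betweenness, avg_closeness, trend), `hubs_a`, `hubs_b`
#'   (per-network hub ID sets) and `degree_threshold`. An empty intersection
#'   is a valid empty report.
#' @export
common_hub_report <- function(cent_a, cent_b, trends = NULL,
                              degree_threshold = 15) {
  hubs_a <- identify_hubs(cent_a, degree_threshold)
  hubs_b <- identify_hubs(cent_b, degree_threshold)
  common <- intersect(hubs_a, hubs_b)
  ia <- match(common, cent_a$node)
  ib <- match(common, cent_b$node)
  df <- data.frame(
    mirna = common,
    avg_degree = (cent_a$degree[ia] + cent_b$degree[ib]) / 2,
    avg_betweenness = (cent_a$betweenness[ia] + cent_b$betweenness[ib]) / 2,
    avg_closeness = (cent_a$closeness[ia] + cent_b$closeness[ib]) / 2,
    trend = if (is.null(trends)) rep(NA_character_, length(common)) else
      unname(trends[common]),
    stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$avg_degree, -df$avg_betweenness, df$mirna), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(list(common_hubs = df, hubs_a = sort(hubs_a),
                 hubs_b = sort(hubs_b),
                 degree_threshold = degree_threshold),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hub_report: %d common hubs (degree >= %s; %d in network A, %d in network B)\n",
              nrow(x$common_hubs), format(x$degree_threshold),
              length(x$hubs_a), length(x$hubs_b)))
  if (nrow(x$common_hubs) > 0) print(utils::head(x$common_hubs, 10))
  invisible(x)
}
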