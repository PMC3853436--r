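## End-to-end pipeline: differential filter -> expression network ->
## target-activity network -> topology -> common hubs -> validation battery.
## All outputs are plain-text TSV/JSON and byte-reproducible given the seed.

#' Run the full dual-network miRNA discovery pipeline
#'
#' Stages: (1) permutation SAM filter on the miRNA matrix and selection of
#' differentially expressed miRNAs (p < 0.05, FDR < 0.1) with strict-trend
#' labels; (2) MI network on their expression; (3) target-activity scores
#' from the mRNA matrix and a second MI network on them; (4) centralities,
#' summary statistics and top-degree removal curves for both networks;
#' (5) Poisson-null threshold advice and the common-hub report; (6) the
#' validation battery comparing the common-hub set against the full
#' differential set (four classifiers on both matrices), the random-set
#' correlation test, the global test, and -- when a survival table is given
#' -- the K-means/log-rank comparison.
#'
#' @param mirna miRNA feature-by-sample matrix with two-class labels
#'   (attribute or `labels` argument).
#' @param mrna mRNA gene-by-sample matrix over the same samples.
#' @param targets named list miRNA -> target gene IDs.
#' @param labels two-class sample labels.
#' @param survival optional survival table (sample_id, time, event).
#' @param pool_ids optional disease-miRNA pool for the random-set test
#'   (default: all selected differential miRNAs).
#' @param out_dir optional directory; when given, every stage's tables are
#'   written there as TSV/JSON (see Details in the package vignette).
#' @param seed master integer seed; each stochastic stage uses a fixed
#'   offset from it.
#' @param n_perm label permutations for the differential filter.
#' @param k_neighbors,epsilon MI estimator and DPI parameters.
#' @param degree_threshold hub degree threshold (default 15).
#' @param global_perm permutations for the global test.
#' @param n_iter draws for the random-set correlation test.
#' @param rf_trees random-forest size for the classifier battery.
#' @param classifiers classifier subset to run.
#' @return a `pipeline_result` list: `diffexpr`, `selected`, `trends`,
#'   `network_expression`, `network_activity`, `activity`, `centralities`
#'   (list a/b), `summary` (two-row data.frame), `removal` (list a/b),
#'   `hub_report`, `threshold_advice`, `classification`, `random_test`,
#'   `global_test`, `survival_comparison` (or NULL).
#' @examples
#' \donttest{
#' sim <- generate_dual_dataset(synthetic_config(n_mirna = 40, n_hubs = 4,
#'                                               n_genes = 300, seed = 2))
#' res <- run_pipeline(sim$mirna, sim$mrna, sim$targets,
#'                     survival = sim$survival, seed = 2, n_perm = 200,
#'                     rf_trees = 500, degree_threshold = 5)
#' res$hub_report
#' }
#' @export
run_pipeline <- function(mirna, mrna, targets,
                         labels = sample_labels(mirna), survival = NULL,
                         pool_ids = NULL, out_dir = NULL, seed = 1L,
                         n_perm = 1000, k_neighbors = 3, epsilon = 0.05,
                         degree_threshold = 15, global_perm = 10000,
                         n_iter = 1000, rf_trees = 5000,
                         classifiers = c("naive_bayes", "knn", "svm_rbf",
                                         "random_forest")) {
  seed <- as.integer(seed)
  sample_labels(mirna) <- labels

  ## 1. differential expression filter + trends
  de <- permutation_test(mirna, labels, n_perm = n_perm, seed = seed)
  selected <- select_differential(de)
  trends <- assign_trend(de)
  if (length(selected) < 3)
    stop_input("only %d differentially expressed miRNA(s) selected; nothing to network",
               length(selected))

  ## 2. network from miRNA expression
  net_a <- build_network(mirna[selected, , drop = FALSE],
                         k_neighbors = k_neighbors, epsilon = epsilon)

  ## 3. target-activity scores and second network
  act <- activity_scores(mrna, targets,
                         mirna_ids = intersect(selected, names(targets)))
  low_var <- flag_low_variance(act)
  net_b <- build_network(act$scores, k_neighbors = k_neighbors,
                         epsilon = epsilon)

  ## 4. topology
  cent_a <- node_centralities(net_a)
  cent_b <- node_centralities(net_b)
  summary_df <- rbind(
    cbind(network = "expression", network_summary(net_a)),
    cbind(network = "activity", network_summary(net_b)))
  top_n <- min(10L, igraph::vcount(net_a) - 1L, igraph::vcount(net_b) - 1L)
  removal <- list(expression = removal_curve(net_a, top_n),
                  activity = removal_curve(net_b, top_n))

  ## 5. hubs
  advice <- data.frame(
    network = c("expression", "activity"),
    avg_degree = c(summary_df$avg_degree),
    suggested_threshold = c(
      suggest_threshold(max(summary_df$avg_degree[1], 1e-8)),
      suggest_threshold(max(summary_df$avg_degree[2], 1e-8))),
    row.names = NULL)
  hubs <- common_hub_report(cent_a, cent_b, trends = trends,
                            degree_threshold = degree_threshold)
  hub_ids <- hubs$common_hubs$mirna

  ## 6. validation battery
  feature_sets <- list(common_hubs = hub_ids, differential = selected)
  matrices <- list(expression = mirna, activity = act$scores)
  rows <- list()
  for (mk in names(matrices)) {
    for (fs in names(feature_sets)) {
      ids <- intersect(feature_sets[[fs]], rownames(matrices[[mk]]))
      if (length(ids) < 1) next
      for (clf in classifiers) {
        rep <- crossval_accuracy(matrices[[mk]], labels, ids, clf,
                                 seed = seed + 101L, rf_trees = rf_trees)
        rows[[length(rows) + 1]] <- data.frame(
          matrix_kind = mk, feature_set = fs, classifier = clf,
          n_features = length(ids), accuracy = rep$accuracy,
          stringsAsFactors = FALSE)
      }
    }
  }
  classification <- do.call(rbind, rows)

  if (is.null(pool_ids)) pool_ids <- selected
  random_test <- if (length(hub_ids) >= 2 &&
                     length(pool_ids) >= length(hub_ids)) {
    random_set_correlation_test(mirna, hub_ids, pool_ids, n_iter = n_iter,
                                seed = seed + 202L)
  }
  gt <- if (length(hub_ids) >= 1)
    global_test(mirna, labels, hub_ids, n_perm = global_perm,
                seed = seed + 303L)
  surv_cmp <- if (!is.null(survival) && length(hub_ids) >= 1)
    survival_compare(mirna, hub_ids, labels, survival, seed = seed + 404L)

  res <- structure(list(
    diffexpr = de, selected = selected, trends = trends,
    network_expression = net_a, network_activity = net_b, activity = act,
    low_variance_flagged = low_var,
    centralities = list(expression = cent_a, activity = cent_b),
    summary = summary_df, removal = removal, threshold_advice = advice,
    hub_report = hubs, classification = classification,
    random_test = random_test, global_test = gt,
    survival_comparison = surv_cmp, seed = seed),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Generate a synthetic dataset and run the pipeline on it
#'
#' Convenience wrapper: [generate_dual_dataset()] followed by
#' [run_pipeline()], returning both the simulation (with its planted truth)
#' and the pipeline result.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory (see [run_pipeline()]).
#' @param seed master pipeline seed (default: the config's seed).
#' @param ... further arguments to [run_pipeline()].
#' @return list with elements `sim` and `result`.
#' @export
run_synthetic_pipeline <- function(config, out_dir = NULL,
                                   seed = config$seed, ...) {
  sim <- generate_dual_dataset(config)
  res <- run_pipeline(sim$mirna, sim$mrna, sim$targets,
                      survival = sim$survival, out_dir = out_dir,
                      seed = seed, ...)
  list(sim = sim, result = res)
}

# Write every stage's outputs as deterministic TSV/JSON.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  de <- as.data.frame(res$diffexpr)
  for (col in c("mean_a", "mean_b", "d", "p_value", "fdr"))
    de[[col]] <- format_num(de[[col]])
  write_tsv(de, p("diffexpr.tsv"))
  writeLines(res$selected, p("selected_mirnas.txt"))

  write_edge_list(res$network_expression, p("network_expression_edges.tsv"))
  write_edge_list(res$network_activity, p("network_activity_edges.tsv"))
  write_graphml(res$network_expression, p("network_expression.graphml"),
                res$centralities$expression)
  write_graphml(res$network_activity, p("network_activity.graphml"),
                res$centralities$activity)

  write_expression(res$activity$scores, p("activity_matrix.tsv"),
                   feature_col = "mirna")
  write_tsv(data.frame(mirna = names(res$activity$var_explained),
                       n_targets_used = unname(res$activity$n_targets_used),
                       var_explained = format_num(unname(res$activity$var_explained)),
                       stringsAsFactors = FALSE),
            p("activity_report.tsv"))

  for (nm in c("expression", "activity")) {
    cent <- res$centralities[[nm]]
    for (col in c("betweenness", "closeness", "clustering"))
      cent[[col]] <- format_num(cent[[col]])
    write_tsv(cent, sprintf("%s/centralities_%s.tsv", out_dir, nm))
    rem <- res$removal[[nm]]
    rem$avg_degree <- format_num(rem$avg_degree)
    rem$char_path_length <- format_num(rem$char_path_length)
    write_tsv(rem, sprintf("%s/removal_curve_%s.tsv", out_dir, nm))
  }
  sm <- res$summary
  for (col in setdiff(colnames(sm), c("network", "n_nodes", "n_edges")))
    sm[[col]] <- format_num(sm[[col]])
  write_tsv(sm, p("topology_summary.tsv"))
  jsonlite::write_json(res$summary, p("topology_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  hub_df <- res$hub_report$common_hubs
  for (col in c("avg_degree", "avg_betweenness", "avg_closeness"))
    hub_df[[col]] <- format_num(hub_df[[col]])
  write_tsv(hub_df, p("hub_report.tsv"))
  jsonlite::write_json(
    list(common_hub_ids = res$hub_report$common_hubs$mirna,
         hubs_expression = res$hub_report$hubs_a,
         hubs_activity = res$hub_report$hubs_b,
         degree_threshold = res$hub_report$degree_threshold,
         threshold_advice = res$threshold_advice),
    p("hub_report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")

  cl <- res$classification
  cl$accuracy <- format_num(cl$accuracy)
  write_tsv(cl, p("classification_report.tsv"))

  if (!is.null(res$random_test))
    jsonlite::write_json(
      list(candidate_mean_r = res$random_test$candidate_mean_r,
           empirical_p = res$random_test$empirical_p,
           max_null_mean = max(res$random_test$null_means),
           n_iter = length(res$random_test$null_means)),
      p("random_test.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$global_test)) {
    jsonlite::write_json(list(Q = res$global_test$Q,
                              p_value = res$global_test$p_value,
                              n_perm = res$global_test$n_perm),
                         p("global_test.json"), auto_unbox = TRUE,
                         digits = NA)
    pf <- res$global_test$per_feature
    pf$contribution <- format_num(pf$contribution)
    pf$p_value <- format_num(pf$p_value)
    write_tsv(pf, p("global_test_features.tsv"))
  }
  if (!is.null(res$survival_comparison)) {
    sc <- res$survival_comparison
    jsonlite::write_json(list(statistic = sc$statistic,
                              p_value = sc$p_value,
                              groups = as.list(sc$groups)),
                         p("survival_comparison.json"), auto_unbox = TRUE,
                         digits = NA)
    km <- sc$km
    km$time <- format_num(km$time)
    km$survival <- format_num(km$survival)
    write_tsv(km, p("km_curves.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (seed %d)\n", x$seed))
  cat(sprintf("  selected differential miRNAs: %d\n", length(x$selected)))
  cat(sprintf("  expression network: %d edges | activity network: %d edges\n",
              igraph::ecount(x$network_expression),
              igraph::ecount(x$network_activity)))
  cat(sprintf("  common hubs (degree >= %s): %d\n",
              format(x$hub_report$degree_threshold),
              nrow(x$hub_report$common_hubs)))
  if (!is.null(x$global_test))
    cat(sprintf("  global test: Q = %.3f, p = %.3g\n", x$global_test$Q,
                x$global_test$p_value))
  if (!is.null(x$survival_comparison))
    cat(sprintf("  log-rank: chisq = %.3f, p = %.4f\n",
                x$survival_comparison$statistic,
                x$survival_comparison$p_value))
  invisible(x)
}
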