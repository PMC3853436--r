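## Validation battery for a candidate miRNA set: cross-validated subtype
## classification, a random-set correlation test against a disease-miRNA
## pool, a Goeman-style global association test, and K-means + log-rank
## survival comparison.

#' Cross-validated subtype classification accuracy of a feature set
#'
#' Mean held-out accuracy over stratified k-fold cross-validation for one of
#' four classifiers with the battery's fixed settings: Gaussian naive Bayes,
#' kNN with `k = 3`, SVM with an RBF kernel (library defaults for cost and
#' bandwidth, recorded in the report), and a random forest of 5,000 trees.
#'
#' @param values numeric feature-by-sample matrix.
#' @param labels two-class sample labels (default: attached labels).
#' @param feature_ids features used as predictors (must exist in `values`).
#' @param classifier one of `"naive_bayes"`, `"knn"`, `"svm_rbf"`,
#'   `"random_forest"`.
#' @param folds number of stratified CV folds (default 5); every class needs
#'   at least `folds` samples.
#' @param seed integer RNG seed (fold assignment and stochastic fits).
#' @param rf_trees random-forest tree count (default 5000).
#' @param knn_k kNN neighbour count (default 3).
#' @return a `classification_report`: list with `accuracy` (mean over
#'   folds), `fold_accuracy`, `folds` (named fold assignment), `classifier`,
#'   `settings`, `seed`.
#' @export
crossval_accuracy <- function(values, labels = sample_labels(values),
                              feature_ids = rownames(values),
                              classifier = c("naive_bayes", "knn", "svm_rbf",
                                             "random_forest"),
                              folds = 5, seed = 1L, rf_trees = 5000,
                              knn_k = 3) {
  classifier <- match.arg(classifier)
  missing <- setdiff(feature_ids, rownames(values))
  if (length(missing) > 0)
    stop_input("feature ID(s) missing from matrix: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  cls <- split_classes(labels, colnames(values))
  y <- factor(cls$labels, levels = cls$classes)
  if (min(table(y)) < folds)
    stop_input("every class needs >= %d samples for %d-fold stratified CV",
               folds, folds)
  X <- t(values[feature_ids, , drop = FALSE])

  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in cls$classes) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    settings <- switch(classifier,
      naive_bayes = list(),
      knn = list(k = knn_k),
      svm_rbf = list(kernel = "radial", cost = 1,
                     gamma = 1 / length(feature_ids)),
      random_forest = list(ntree = rf_trees))
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f; te <- !tr
      pred <- switch(classifier,
        naive_bayes = {
          fit <- e1071::naiveBayes(X[tr, , drop = FALSE], y[tr])
          predict(fit, data.frame(X[te, , drop = FALSE], check.names = FALSE))
        },
        knn = class::knn(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                         y[tr], k = knn_k),
        svm_rbf = {
          fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial")
          predict(fit, X[te, , drop = FALSE])
        },
        random_forest = {
          fit <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                            ntree = rf_trees)
          predict(fit, X[te, , drop = FALSE])
        })
      mean(as.character(pred) == as.character(y[te]))
    }, numeric(1))
    structure(list(accuracy = mean(acc), fold_accuracy = acc,
                   folds = stats::setNames(fold, colnames(values)),
                   classifier = classifier, settings = settings,
                   seed = as.integer(seed)),
              class = "classification_report")
  })
}

#' Random-set correlation test for a candidate miRNA set
#'
#' Compares the mean pairwise Pearson correlation of the candidate set with
#' the null distribution obtained by repeatedly drawing same-size sets (no
#' replacement) from a reference pool of disease-related miRNAs.
#'
#' @inheritParams crossval_accuracy
#' @param candidate_ids candidate feature set (>= 2 features).
#' @param pool_ids reference pool to draw null sets from (subset of the
#'   matrix features).
#' @param set_size size of each null draw (default: candidate set size).
#' @param n_iter number of null draws (default 1000).
#' @param absolute average `|r|` instead of signed `r`.
#' @param seed integer RNG seed.
#' @return list with `candidate_mean_r`, `null_means` (length `n_iter`),
#'   and `empirical_p = (1 + #{null >= candidate}) / (1 + n_iter)`.
#' @export
random_set_correlation_test <- function(values, candidate_ids, pool_ids,
                                        set_size = length(candidate_ids),
                                        n_iter = 1000, absolute = FALSE,
                                        seed = 1L) {
  if (length(candidate_ids) < 2 || set_size < 2)
    stop_input("'candidate_ids' and 'set_size' must be >= 2")
  missing <- setdiff(c(candidate_ids, pool_ids), rownames(values))
  if (length(missing) > 0)
    stop_input("feature ID(s) missing from matrix: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  if (set_size > length(pool_ids))
    stop_input("'set_size' (%d) exceeds pool size (%d)", set_size,
               length(pool_ids))
  mean_pair_r <- function(C) {
    v <- C[upper.tri(C)]
    if (absolute) v <- abs(v)
    mean(v)
  }
  cand <- mean_pair_r(cor(t(values[candidate_ids, , drop = FALSE])))
  pool_cor <- cor(t(values[pool_ids, , drop = FALSE]))
  null_means <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(length(pool_ids), set_size)
      mean_pair_r(pool_cor[idx, idx, drop = FALSE])
    }, numeric(1))
  })
  list(candidate_mean_r = cand, null_means = null_means,
       empirical_p = (1 + sum(null_means >= cand)) / (1 + n_iter))
}

#' Global association test between a feature set and the class outcome
#'
#' Score-type test of whether the joint expression pattern of a feature set
#' is associated with the two-class outcome: with `y` the centred class
#' indicator and `X` the row-standardised feature submatrix,
#' `Q = sum_j (x_j' y)^2 / m`. Significance is assessed by label
#' permutation, and each feature's contribution `(x_j' y)^2` gets its own
#' permutation p-value from the same permutations.
#'
#' @inheritParams crossval_accuracy
#' @param n_perm number of label permutations (>= 1000).
#' @return a `global_test_result`: list with `Q`, `p_value`, and
#'   `per_feature` (data.frame: feature, contribution, p_value).
#' @export
global_test <- function(values, labels = sample_labels(values),
                        feature_ids = rownames(values), n_perm = 10000,
                        seed = 1L) {
  if (!is.numeric(n_perm) || n_perm < 1000)
    stop_input("'n_perm' must be >= 1000")
  n_perm <- as.integer(n_perm)
  missing <- setdiff(feature_ids, rownames(values))
  if (length(missing) > 0)
    stop_input("feature ID(s) missing from matrix: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  cls <- split_classes(labels, colnames(values))
  y <- as.numeric(cls$b)
  y <- y - mean(y)
  X <- values[feature_ids, , drop = FALSE]
  mu <- rowMeans(X)
  sdev <- apply(X, 1, stats::sd)
  sdev[sdev == 0] <- Inf  # constant features contribute 0
  X <- (X - mu) / sdev
  m <- nrow(X)
  score <- as.numeric(X %*% y)
  Q <- sum(score^2) / m
  perm <- with_seed(seed, {
    Y <- vapply(seq_len(n_perm), function(i) y[sample.int(length(y))],
                numeric(length(y)))
    S2 <- (X %*% Y)^2
    list(Qnull = colSums(S2) / m,
         feat_ge = rowSums(S2 >= score^2 - 1e-15))
  })
  structure(list(
    Q = Q,
    p_value = (1 + sum(perm$Qnull >= Q - 1e-15)) / (1 + n_perm),
    per_feature = data.frame(feature = feature_ids,
                             contribution = score^2,
                             p_value = (1 + perm$feat_ge) / (1 + n_perm),
                             stringsAsFactors = FALSE, row.names = NULL),
    n_perm = n_perm, seed = as.integer(seed)),
    class = "global_test_result")
}

#' K-means grouping and log-rank survival comparison
#'
#' Samples are clustered into two groups by K-means on the candidate-feature
#' expression profiles (10 seeded restarts); each group is labelled by its
#' majority true subtype ("<class>_trend"), and the two groups' survival is
#' compared with the standard observed-minus-expected log-rank test.
#' Kaplan-Meier curves are returned per group for plotting.
#'
#' @inheritParams crossval_accuracy
#' @param survival data.frame (sample_id, time, event) covering the matrix
#'   samples (see [read_survival()]).
#' @return a `survival_comparison`: list with `groups` (named group label
#'   per sample), `statistic` (log-rank chi-square), `p_value`, and `km`
#'   (data.frame: time, survival, group). If clustering degenerates to a
#'   single non-empty group the report carries `p_value = 1` with a warning.
#' @export
survival_compare <- function(values, feature_ids = rownames(values),
                             labels = sample_labels(values), survival,
                             seed = 1L) {
  missing <- setdiff(feature_ids, rownames(values))
  if (length(missing) > 0)
    stop_input("feature ID(s) missing from matrix: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  cls <- split_classes(labels, colnames(values))
  surv_missing <- setdiff(colnames(values), survival$sample_id)
  if (length(surv_missing) > 0)
    stop_input("survival table is missing sample(s): %s",
               paste(utils::head(surv_missing, 5), collapse = ", "))
  X <- t(values[feature_ids, , drop = FALSE])
  km_fit <- with_seed(seed, kmeans(X, centers = 2, nstart = 10))
  cluster <- km_fit$cluster
  group <- character(length(cluster))
  for (k in 1:2) {
    in_k <- cluster == k
    n_a <- sum(cls$a[in_k]); n_b <- sum(cls$b[in_k])
    maj <- if (n_a >= n_b) cls$classes[1] else cls$classes[2]
    group[in_k] <- paste0(maj, "_trend")
  }
  # both clusters may land on the same majority subtype; keep them distinct
  if (length(unique(group)) == 1 && length(unique(cluster)) == 2)
    group <- paste0(group, c("_1", "_2")[cluster])
  names(group) <- colnames(values)
  sv <- survival[match(colnames(values), survival$sample_id), ]
  if (length(unique(group)) < 2) {
    warning("all samples fell in one cluster: log-rank test undefined, p = 1",
            call. = FALSE)
    return(structure(list(groups = group, statistic = NA_real_, p_value = 1,
                          km = km_curves(sv, group)),
                     class = "survival_comparison"))
  }
  sd_fit <- survival::survdiff(
    survival::Surv(sv$time, sv$event) ~ group)
  structure(list(groups = group, statistic = unname(sd_fit$chisq),
                 p_value = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
                 km = km_curves(sv, group)),
            class = "survival_comparison")
}

# Kaplan-Meier curves as a tidy (time, survival, group) table
km_curves <- function(sv, group) {
  out <- lapply(sort(unique(group)), function(g) {
    in_g <- group == g
    fit <- survival::survfit(survival::Surv(sv$time[in_g], sv$event[in_g]) ~ 1)
    data.frame(time = c(0, fit$time), survival = c(1, fit$surv), group = g,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
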