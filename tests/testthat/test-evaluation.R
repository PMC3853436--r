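sep_matrix <- function(n_a = 10, n_b = 15, seed = 1) {
  set.seed(seed)
  m <- rbind(sep = c(rnorm(n_a, -4), rnorm(n_b, 4)),
             noise1 = rnorm(n_a + n_b), noise2 = rnorm(n_a + n_b))
  colnames(m) <- sprintf("s%02d", seq_len(n_a + n_b))
  attr(m, "labels") <- setNames(rep(c("basal_like", "luminal_A"),
                                    c(n_a, n_b)), colnames(m))
  m
}

test_that("a perfectly separating feature gives accuracy 1 for all classifiers", {
  m <- sep_matrix()
  for (clf in c("naive_bayes", "knn", "svm_rbf", "random_forest")) {
    rep <- crossval_accuracy(m, feature_ids = "sep", classifier = clf,
                             seed = 5, rf_trees = 300)
    expect_equal(rep$accuracy, 1, info = clf)
    expect_length(rep$fold_accuracy, 5)
    # folds partition the samples and are stratified
    expect_setequal(names(rep$folds), colnames(m))
    tab <- table(rep$folds, sample_labels(m))
    expect_true(all(tab[, 1] %in% c(2, 2)) && all(tab[, 2] == 3))
  }
})

test_that("null features give chance-level accuracy and errors are informative", {
  set.seed(2)
  m <- matrix(rnorm(20 * 30), 20,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:30)))
  lab <- setNames(sample(rep(c("basal_like", "luminal_A"), c(12, 18))),
                  colnames(m))
  accs <- sapply(1:5, function(s)
    crossval_accuracy(m, lab, classifier = "knn", seed = s)$accuracy)
  expect_lt(abs(mean(accs) - 0.6), 0.16)  # majority fraction 18/30
  expect_error(crossval_accuracy(m, lab, feature_ids = c("f01", "zz")), "zz")
  expect_error(crossval_accuracy(m, lab, classifier = "perceptron"))
  expect_error(crossval_accuracy(m[, 1:8], lab[1:8], folds = 5), "5-fold")
})

test_that("cross-validation is reproducible given the seed", {
  m <- sep_matrix(seed = 3)
  r1 <- crossval_accuracy(m, classifier = "random_forest", seed = 7,
                          rf_trees = 200)
  r2 <- crossval_accuracy(m, classifier = "random_forest", seed = 7,
                          rf_trees = 200)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$folds, r2$folds)
})

test_that("random-set correlation test handles degenerate and planted cases", {
  set.seed(4)
  m <- matrix(rnorm(10 * 40), 10,
              dimnames = list(sprintf("f%02d", 1:10), NULL))
  # degenerate pool: every draw IS the candidate set -> p = 1
  r <- random_set_correlation_test(m, c("f01", "f02", "f03"),
                                   pool_ids = c("f01", "f02", "f03"),
                                   n_iter = 100, seed = 1)
  expect_equal(r$empirical_p, 1)
  expect_true(all(r$null_means == r$candidate_mean_r))
  # two identical features have mean pairwise r = 1
  m2 <- rbind(a = rnorm(30), b = 0, c = rnorm(30))
  m2["b", ] <- m2["a", ]
  r2 <- random_set_correlation_test(m2, c("a", "b"), rownames(m2),
                                    n_iter = 100, seed = 1)
  expect_equal(r2$candidate_mean_r, 1)
  expect_error(random_set_correlation_test(m, "f01", rownames(m)), ">= 2")
})

test_that("a planted correlated module is detected against an independent pool", {
  cfg <- synthetic_config(n_class_a = 100, n_class_b = 100, n_mirna = 60,
                          n_hubs = 1, module_size = 5, rho = 0.9,
                          de_fraction = 0, n_genes = 100, seed = 6)
  sim <- generate_dual_dataset(cfg)
  mod <- c(sim$truth$hub_ids, sim$truth$module_members[[1]])
  pool <- setdiff(rownames(sim$mirna), mod)
  r <- random_set_correlation_test(sim$mirna, mod, pool, n_iter = 1000,
                                   seed = 2)
  expect_lte(r$empirical_p, 0.01)
  expect_gt(r$candidate_mean_r, max(r$null_means))
})

test_that("global test statistic behaves as a quadratic score statistic", {
  m <- sep_matrix(seed = 8)
  lab <- sample_labels(m)
  g1 <- global_test(m, lab, rownames(m), n_perm = 1000, seed = 1)
  expect_gte(g1$Q, 0)
  # minimal achievable p for a feature equal to the class indicator
  expect_lte(g1$p_value, 0.01)
  expect_equal(nrow(g1$per_feature), 3)
  # invariance to feature reordering
  g2 <- global_test(m[c(3, 1, 2), ], lab, rownames(m)[c(3, 1, 2)],
                    n_perm = 1000, seed = 1)
  expect_equal(g2$Q, g1$Q, tolerance = 1e-12)
  # invariance to flipping the class coding: swap the label strings
  flipped <- setNames(ifelse(lab == "basal_like", "a_luminal", "b_basal"),
                      names(lab))
  g3 <- global_test(m, flipped, rownames(m), n_perm = 1000, seed = 1)
  expect_equal(g3$Q, g1$Q, tolerance = 1e-12)
  expect_error(global_test(m, lab, rownames(m), n_perm = 100), "n_perm")
  expect_error(global_test(m, setNames(rep("x", ncol(m)), colnames(m)),
                           rownames(m)), "2 classes")
})

test_that("log-rank statistic matches the hand-worked observed/expected oracle", {
  # 6 samples, times 1..6 alternating groups, no censoring
  time <- 1:6
  event <- rep(1L, 6)
  group <- rep(c("g1", "g2"), 3)
  orc <- oracle_logrank(time, event, group)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(unname(fit$chisq), orc, tolerance = 1e-9)

  # the same oracle agrees with survival_compare end-to-end: build a matrix
  # whose k-means split reproduces the alternating groups
  m <- rbind(f1 = ifelse(group == "g1", -5, 5) + rnorm(6, sd = 0.01))
  colnames(m) <- sprintf("s%d", 1:6)
  lab <- setNames(rep(c("basal_like", "luminal_A"), 3), colnames(m))
  sv <- data.frame(sample_id = colnames(m), time = time, event = event)
  res <- survival_compare(m, "f1", lab, sv, seed = 1)
  expect_equal(res$statistic, orc, tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(orc, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("identical survival in both groups gives statistic 0 and label swap changes nothing", {
  time <- rep(c(2, 4, 6, 8), each = 2)
  event <- rep(1L, 8)
  group <- rep(c("g1", "g2"), 4)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(unname(fit$chisq), 0, tolerance = 1e-12)
  swapped <- ifelse(group == "g1", "g2", "g1")
  expect_equal(oracle_logrank(time, event, group),
               oracle_logrank(time, event, swapped), tolerance = 1e-12)
})

test_that("groups are named by their majority subtype and KM curves are emitted", {
  set.seed(9)
  n_a <- 8; n_b <- 12
  m <- rbind(f1 = c(rnorm(n_a, -4), rnorm(n_b, 4)), f2 = rnorm(n_a + n_b))
  colnames(m) <- sprintf("s%02d", 1:(n_a + n_b))
  lab <- setNames(rep(c("basal_like", "luminal_A"), c(n_a, n_b)), colnames(m))
  sv <- data.frame(sample_id = colnames(m), time = rexp(n_a + n_b, 0.1),
                   event = rbinom(n_a + n_b, 1, 0.8))
  res <- survival_compare(m, rownames(m), lab, sv, seed = 2)
  expect_setequal(unique(res$groups),
                  c("basal_like_trend", "luminal_A_trend"))
  # k-means on the separating feature recovers the subtype split
  expect_equal(unname(res$groups[1:n_a]), rep("basal_like_trend", n_a))
  expect_true(all(c("time", "survival", "group") %in% colnames(res$km)))
  expect_true(all(res$km$survival >= 0 & res$km$survival <= 1))
})

test_that("strong planted hazard ratios are detected by the log-rank test", {
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(n_class_a = 100, n_class_b = 100, n_mirna = 8,
                            n_hubs = 1, module_size = 2, de_fraction = 0.5,
                            effect_size = 4, n_genes = 30, hazard_ratio = 4,
                            seed = s)
    sim <- generate_dual_dataset(cfg)
    # strong DE features make k-means recover the true classes, so the
    # group split aligns with the planted hazard difference
    de <- sim$truth$de_ids$mirna
    res <- survival_compare(sim$mirna, de, sample_labels(sim$mirna),
                            sim$survival, seed = s)
    hits <- hits + (res$p_value < 0.01)
  }
  expect_gte(hits / 10, 0.9)
})
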