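## Permutation-based SAM-style differential expression between two sample
## classes, with the dual thresholds used downstream: a relaxed filter
## (P < 0.05, FDR < 0.1) to select the working miRNA set, and a stricter one
## (P < 0.001, FDR < 0.05) to label each miRNA with a subtype trend.

#' SAM-style moderated d-statistic
#'
#' For each feature, `d = (mean_a - mean_b) / (s + s0)` where `s` is the
#' pooled standard error of the mean difference and `s0` a small positive
#' fudge factor that damps features with tiny variance. Class "a" is the
#' alphabetically first class label.
#'
#' @param values numeric feature-by-sample matrix.
#' @param labels two-class sample labels (named vector, or in sample order);
#'   taken from `sample_labels(values)` when omitted.
#' @param s0 fudge factor; default (`NULL`) is the median of the per-feature
#'   pooled standard errors.
#' @return data.frame (feature, mean_a, mean_b, s, d) with the classes,
#'   and the `s0` actually used, as attributes.
#' @export
sam_statistic <- function(values, labels = sample_labels(values), s0 = NULL) {
  cls <- split_classes(labels, colnames(values))
  na <- sum(cls$a); nb <- sum(cls$b)
  if (na < 2 || nb < 2)
    stop_input("each class needs >= 2 samples (found %d and %d)", na, nb)
  st <- sam_d(values, cls$a, cls$b, s0)
  out <- data.frame(feature = rownames(values), mean_a = st$mean_a,
                    mean_b = st$mean_b, s = st$s, d = st$d,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "classes") <- cls$classes
  attr(out, "s0") <- st$s0
  out
}

# vectorized d over columns-split masks; s0 = NULL -> median(s)
sam_d <- function(values, a, b, s0 = NULL) {
  na <- sum(a); nb <- sum(b)
  mean_a <- rowMeans(values[, a, drop = FALSE])
  mean_b <- rowMeans(values[, b, drop = FALSE])
  ss_a <- rowSums((values[, a, drop = FALSE] - mean_a)^2)
  ss_b <- rowSums((values[, b, drop = FALSE] - mean_b)^2)
  s <- sqrt((1 / na + 1 / nb) * (ss_a + ss_b) / (na + nb - 2))
  if (is.null(s0)) s0 <- stats::median(s)
  if (!is.numeric(s0) || length(s0) != 1 || is.na(s0) || s0 < 0)
    stop_input("'s0' must be a single number >= 0")
  list(mean_a = mean_a, mean_b = mean_b, s = s,
       d = (mean_a - mean_b) / (s + s0), s0 = s0)
}

#' Permutation test on the SAM d-statistic
#'
#' Class labels are permuted `n_perm` times; the permuted statistics of all
#' features form one pooled null, so p-value resolution is
#' `1 / (1 + n_perm * n_features)` rather than `1 / (1 + n_perm)`. Two-sided
#' p-values are `(1 + #{pooled |d*| >= |d_i|}) / (1 + n_perm * m)`; FDR is
#' Benjamini-Hochberg over those p-values.
#'
#' @inheritParams sam_statistic
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer RNG seed; results are deterministic given it.
#' @return a `diffexpr_result` data.frame: feature, mean_a, mean_b, d,
#'   p_value, fdr, trend (filled by [assign_trend()], initially from the
#'   default thresholds).
#' @examples
#' sim <- generate_dual_dataset(synthetic_config(n_mirna = 25, n_hubs = 2,
#'                                               n_genes = 100, seed = 3))
#' res <- permutation_test(sim$mirna, n_perm = 200, seed = 3)
#' head(res[order(res$p_value), ])
#' @export
permutation_test <- function(values, labels = sample_labels(values),
                             n_perm = 1000, s0 = NULL, seed = 1L) {
  if (!is.numeric(n_perm) || n_perm < 100)
    stop_input("'n_perm' must be >= 100")
  n_perm <- as.integer(n_perm)
  cls <- split_classes(labels, colnames(values))
  obs <- sam_statistic(values, cls$labels, s0)
  s0_used <- attr(obs, "s0")
  n <- ncol(values); na <- sum(cls$a)
  m <- nrow(values)

  # permuted class-A masks as an n x n_perm indicator matrix; group means and
  # sums of squares for every permutation come from two matrix products
  null_d <- with_seed(seed, {
    A <- matrix(0, n, n_perm)
    for (p in seq_len(n_perm)) A[sample.int(n, na), p] <- 1
    B <- 1 - A
    nb <- n - na
    X <- values
    X2 <- values^2
    ma <- (X %*% A) / na
    mb <- (X %*% B) / nb
    ssa <- X2 %*% A - na * ma^2
    ssb <- X2 %*% B - nb * mb^2
    s <- sqrt(pmax(0, (1 / na + 1 / nb) * (ssa + ssb) / (n - 2)))
    (ma - mb) / (s + s0_used)
  })

  null_abs <- sort(abs(as.numeric(null_d)))
  total <- length(null_abs)
  # #{null >= |d_i|} via binary search on the sorted pooled null
  ge <- total - findInterval(abs(obs$d) - 1e-15, null_abs)
  p <- (1 + ge) / (1 + total)
  out <- data.frame(feature = obs$feature, mean_a = obs$mean_a,
                    mean_b = obs$mean_b, d = obs$d, p_value = p,
                    fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "classes") <- cls$classes
  attr(out, "s0") <- s0_used
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  out$trend <- assign_trend(out)
  class(out) <- c("diffexpr_result", class(out))
  out
}

#' Select differentially expressed features
#'
#' The relaxed working filter: features with `p_value < p_max` and
#' `fdr < fdr_max`, input order preserved.
#'
#' @param result a `diffexpr_result` from [permutation_test()].
#' @param p_max,fdr_max selection thresholds.
#' @return character vector of feature IDs.
#' @export
select_differential <- function(result, p_max = 0.05, fdr_max = 0.1) {
  result$feature[result$p_value < p_max & result$fdr < fdr_max]
}

#' Label subtype trends at strict significance
#'
#' A feature is `class_a_trend` when significant at the strict thresholds and
#' its class-A mean exceeds its class-B mean; symmetrically for
#' `class_b_trend`; otherwise (including exactly tied means) `none`.
#'
#' @inheritParams select_differential
#' @param p_max,fdr_max strict significance thresholds for trend calls.
#' @return character vector of trend labels named by feature.
#' @export
assign_trend <- function(result, p_max = 0.001, fdr_max = 0.05) {
  sig <- result$p_value < p_max & result$fdr < fdr_max
  trend <- rep("none", nrow(result))
  trend[sig & result$mean_a > result$mean_b] <- "class_a_trend"
  trend[sig & result$mean_b > result$mean_a] <- "class_b_trend"
  stats::setNames(trend, result$feature)
}
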