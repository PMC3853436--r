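## Target-activity reconstruction: each miRNA's "activity" profile across
## samples is the first principal component of its target genes' mRNA
## expression, so the second interaction network is built over the same
## sample space as the first.

#' Reconstruct miRNA activity scores from target mRNA expression
#'
#' For each miRNA, the submatrix of its mapped target genes present in the
#' mRNA data is centred gene-wise and its first principal component scores
#' (one per sample) become the miRNA's activity profile; the fraction of
#' total variance the component explains is reported alongside. The PCA is on
#' the covariance (not correlation) of the centred genes. The component sign
#' is fixed so the score correlates non-negatively with the mean centred
#' target profile. miRNAs with no mapped target are dropped with a warning;
#' a single-target miRNA gets that gene's centred expression and
#' `var_explained = 1`.
#'
#' @param mrna numeric gene-by-sample expression matrix (>= 2 samples).
#' @param targets named list: miRNA ID -> character vector of gene IDs (e.g.
#'   from [read_target_map()]).
#' @param mirna_ids miRNAs to score (default: all in `targets`).
#' @return an `activity_matrix`: list with `scores` (miRNA x sample matrix),
#'   `var_explained` (named, in `[0, 1]`), and `n_targets_used` (named
#'   counts of target genes found in the mRNA matrix).
#' @examples
#' sim <- generate_dual_dataset(synthetic_config(n_mirna = 10, n_hubs = 1,
#'                                               n_genes = 60, seed = 5))
#' act <- activity_scores(sim$mrna, sim$targets)
#' range(act$var_explained)
#' @export
activity_scores <- function(mrna, targets, mirna_ids = names(targets)) {
  if (length(targets) == 0) stop_input("empty target map")
  if (ncol(mrna) < 2) stop_input("mRNA matrix needs >= 2 samples")
  mirna_ids <- as.character(mirna_ids)
  unknown <- setdiff(mirna_ids, names(targets))
  if (length(unknown) > 0)
    stop_input("miRNA(s) absent from target map: %s",
               paste(utils::head(unknown, 5), collapse = ", "))
  n <- ncol(mrna)
  rows <- vector("list", length(mirna_ids))
  ve <- nt <- stats::setNames(rep(NA_real_, length(mirna_ids)), mirna_ids)
  for (i in seq_along(mirna_ids)) {
    mid <- mirna_ids[i]
    genes <- intersect(targets[[mid]], rownames(mrna))
    nt[i] <- length(genes)
    if (length(genes) == 0) next
    X <- mrna[genes, , drop = FALSE]
    Xc <- X - rowMeans(X)
    pc <- first_pc(Xc)
    rows[[i]] <- pc$score
    ve[i] <- pc$var_explained
  }
  dropped <- mirna_ids[nt == 0]
  if (length(dropped) > 0)
    warning(sprintf("dropped %d miRNA(s) with no mapped target in the mRNA matrix: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  keep <- nt > 0
  scores <- do.call(rbind, rows[keep])
  if (is.null(scores)) scores <- matrix(numeric(0), 0, n)
  dimnames(scores) <- list(mirna_ids[keep], colnames(mrna))
  structure(list(scores = scores,
                 var_explained = ve[keep],
                 n_targets_used = stats::setNames(as.integer(nt[keep]),
                                                  mirna_ids[keep])),
            class = "activity_matrix")
}

# First principal component of a row-centred gene x sample matrix: sample
# scores v1 * d1 from the SVD, variance fraction d1^2 / sum(d^2), sign fixed
# against the mean centred profile.
first_pc <- function(Xc) {
  if (nrow(Xc) == 1)
    return(list(score = as.numeric(Xc), var_explained = 1))
  sv <- svd(Xc, nu = 0, nv = 1)
  tot <- sum(sv$d^2)
  if (tot == 0)
    return(list(score = rep(0, ncol(Xc)), var_explained = 0))
  score <- sv$v[, 1] * sv$d[1]
  mean_profile <- colMeans(Xc)
  ip <- sum(score * mean_profile)
  if (ip < 0) score <- -score
  list(score = score, var_explained = sv$d[1]^2 / tot)
}

#' Flag miRNAs whose first component summarises their targets poorly
#'
#' Reporting aid: IDs whose first principal component explains less than
#' `floor` of the target-set variance (a common rule of thumb for "more
#' components would be needed"). Flagged miRNAs are not removed anywhere in
#' the pipeline.
#'
#' @param activity an `activity_matrix` from [activity_scores()].
#' @param floor variance-explained floor (default 0.40).
#' @return character vector of flagged miRNA IDs.
#' @export
flag_low_variance <- function(activity, floor = 0.40) {
  names(activity$var_explained)[activity$var_explained < floor]
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d miRNAs x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  if (length(x$var_explained) > 0)
    cat(sprintf("  first-PC variance explained: min %.3f, median %.3f\n",
                min(x$var_explained), stats::median(x$var_explained)))
  invisible(x)
}
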