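#' Area under the ROC curve for two response samples
#'
#' Probability that a randomly drawn value from the positive group exceeds a
#' randomly drawn value from the negative group, with ties credited 0.5
#' (the Mann-Whitney identity). Computed from pooled mid-ranks.
#'
#' @param values_pos,values_neg numeric samples from the two trial types.
#' @return auROC in [0, 1].
#' @export
auroc <- function(values_pos, values_neg) {
  n1 <- length(values_pos); n2 <- length(values_neg)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(values_pos, values_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC-based selectivity/modulation index
#'
#' The comparative index used throughout: 2 * (auROC - 0.5), ranging from
#' -1 (negative group always larger) to +1 (positive group always larger).
#'
#' @inheritParams auroc
#' @return list of class `roc_index` with `auroc`, `index`, `n_pos`,
#'   `n_neg` (and, after [permutation_significance()], `p_perm` and
#'   `significant`).
#' @export
roc_index <- function(values_pos, values_neg) {
  a <- auroc(values_pos, values_neg)
  structure(list(auroc = a, index = 2 * (a - 0.5),
                 n_pos = length(values_pos), n_neg = length(values_neg),
                 p_perm = NA_real_, significant = NA),
            class = "roc_index")
}

#' @export
print.roc_index <- function(x, ...) {
  cat(sprintf("ROC index %.4f (auROC %.4f; n = %d vs %d)",
              x$index, x$auroc, x$n_pos, x$n_neg))
  if (!is.na(x$p_perm))
    cat(sprintf("; permutation p = %.4f%s", x$p_perm,
                if (isTRUE(x$significant)) " *" else ""))
  cat("\n")
  invisible(x)
}

#' Permutation significance of a ROC index
#'
#' Trial labels are shuffled `n_perm` times and the index recomputed to
#' build a null distribution; the observed index is significant when it
#' falls outside the central 95% interval of that distribution. The
#' reported two-sided p is 2 * min(tail fractions), capped at 1, with the
#' observed value included in its own tail.
#'
#' @inheritParams auroc
#' @param n_perm number of label shuffles.
#' @param seed integer seed for the shuffles.
#' @param alpha central-interval significance level.
#' @return a `roc_index` with `p_perm` and `significant` filled in.
#' @export
permutation_significance <- function(values_pos, values_neg,
                                     n_perm = 2000, seed = 1,
                                     alpha = 0.05) {
  res <- roc_index(values_pos, values_neg)
  pooled <- c(values_pos, values_neg)
  n1 <- length(values_pos); n <- length(pooled)
  if (length(unique(pooled)) == 1L) {
    res$p_perm <- 1; res$significant <- FALSE
    return(res)
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  null_idx <- vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(n, n1)
    2 * (auroc(pooled[pos], pooled[-pos]) - 0.5)
  }, numeric(1))
  lo <- stats::quantile(null_idx, alpha / 2, names = FALSE, type = 1)
  hi <- stats::quantile(null_idx, 1 - alpha / 2, names = FALSE, type = 1)
  res$significant <- res$index < lo || res$index > hi
  p_hi <- (sum(null_idx >= res$index) + 1) / (n_perm + 1)
  p_lo <- (sum(null_idx <= res$index) + 1) / (n_perm + 1)
  res$p_perm <- min(1, 2 * min(p_hi, p_lo))
  res
}

#' Rank tests for clustered observations
#'
#' Observations recorded from the same imaging field (cluster) are
#' correlated, so pooled rank tests overstate the effective sample size.
#' Each cluster is reduced to its within-cluster mean and the standard
#' Wilcoxon test is applied across clusters: `rank_sum` compares two
#' groups whose labels are constant within a cluster (e.g. brain area),
#' `signed_rank` tests cluster-mean values (e.g. paired differences)
#' against zero. With singleton clusters both reduce exactly to the
#' textbook Wilcoxon tests, and duplicating observations within a cluster
#' leaves the p value unchanged.
#'
#' @param values numeric observations.
#' @param cluster_ids cluster membership, one per observation.
#' @param group_labels two-level group labels (rank_sum only); must be
#'   constant within each cluster.
#' @param method "rank_sum" or "signed_rank".
#' @return list of class `clustered_test` with `statistic`, `p_value`,
#'   `n_clusters`, `method`.
#' @export
clustered_rank_test <- function(values, cluster_ids, group_labels = NULL,
                                method = c("rank_sum", "signed_rank")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(cluster_ids))
  cl <- as.character(cluster_ids)
  n_cl <- length(unique(cl))
  if (n_cl < 2) warning("fewer than 2 clusters; test reduces to pooled data")
  if (method == "rank_sum") {
    if (is.null(group_labels)) stop("rank_sum needs group_labels")
    g <- as.character(group_labels)
    per_cl_g <- tapply(g, cl, function(x) length(unique(x)))
    if (any(per_cl_g > 1))
      stop("group label varies within a cluster; rank_sum requires ",
           "cluster-constant groups")
    m <- tapply(values, cl, mean)
    gm <- tapply(g, cl, `[`, 1)
    lv <- unique(gm)
    if (length(lv) != 2) stop("rank_sum needs exactly 2 groups")
    wt <- stats::wilcox.test(m[gm == lv[1]], m[gm == lv[2]], exact = NULL)
  } else {
    m <- tapply(values, cl, mean)
    wt <- stats::wilcox.test(m, mu = 0, exact = NULL)
  }
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_clusters = n_cl, method = method),
            class = "clustered_test")
}

#' @export
print.clustered_test <- function(x, ...) {
  cat(sprintf("clustered %s test: W = %.1f, p = %.4g (%d clusters)\n",
              x$method, x$statistic, x$p_value, x$n_clusters))
  invisible(x)
}

#' Bootstrap confidence interval on a per-field fraction
#'
#' Population percentages (e.g. fraction of target-preferring neurons) are
#' computed per imaging field; imaging fields are resampled with
#' replacement to obtain a standard error of the across-field mean.
#'
#' @param per_field_values one value per imaging field.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list with `mean`, `se`, `boot_means`.
#' @export
bootstrap_fraction_ci <- function(per_field_values, n_boot = 2000, seed = 1) {
  x <- per_field_values
  stopifnot(length(x) >= 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  bm <- vapply(seq_len(n_boot),
               function(i) mean(x[sample.int(length(x), replace = TRUE)]),
               numeric(1))
  list(mean = mean(x), se = stats::sd(bm), boot_means = bm)
}

# save/restore the global RNG state so seeded helpers do not clobber the
# caller's random stream
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
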