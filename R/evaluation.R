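# Ranking and classification evaluation protocol.
#
# Ground truth is a per-query similarity row (TM-score or oracle); the
# positive set of a query is everything scoring at least rho times the
# query's maximal non-self similarity. Ranking quality is summarized by
# macro-averaged per-query AUROC/AUPRC and the Top-K hit ratio; descriptors
# are probed with a multinomial logistic regression on fold-class labels,
# and methods are compared by a half-resampling paired significance test.

#' Structural neighbors of a query
#'
#' Neighbors are database entries whose ground-truth similarity is at least
#' `rho` times the query's maximal (non-self) similarity; the arg-max itself
#' is therefore always a neighbor.
#'
#' @param sim_row named numeric vector of similarities to the query
#'   (self-pair already excluded).
#' @param rho threshold fraction (default 0.9).
#' @return list with `neighbor_ids`, `tm_max`.
#' @export
define_neighbors <- function(sim_row, rho = 0.9) {
  if (length(sim_row) == 0) stop("empty similarity row")
  tm_max <- max(sim_row)
  list(neighbor_ids = names(sim_row)[sim_row >= rho * tm_max], tm_max = tm_max)
}

#' Top-K hit ratio over a set of queries
#'
#' `Ratio_K = mean_i( N_hit_i / min(K, N_nbr_i) )` where `N_hit_i` counts the
#' query's structural neighbors among the top K of its ranking. At K = 1
#' this reduces to Top-1 accuracy. Queries with zero neighbors are excluded
#' with a warning.
#'
#' @param rankings named list of `ranking_result` (see [rank_database]).
#' @param neighbors named list of neighbor-id character vectors, keyed like
#'   `rankings`.
#' @param K integer cutoff (>= 1).
#' @return hit ratio in [0, 1].
#' @export
topk_hit_ratio <- function(rankings, neighbors, K) {
  stopifnot(K >= 1)
  qids <- names(rankings)
  vals <- numeric(0)
  for (q in qids) {
    nbr <- neighbors[[q]]
    if (length(nbr) == 0) {
      warning("query '", q, "' has no structural neighbors; excluded")
      next
    }
    top <- utils::head(rankings[[q]]$ordered_ids, K)
    vals <- c(vals, sum(top %in% nbr) / min(K, length(nbr)))
  }
  if (length(vals) == 0) stop("no query with neighbors")
  mean(vals)
}

# AUROC by the rank-sum (Mann-Whitney) statistic; ties share ranks.
auroc_from_scores <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# AUPRC by step-wise (non-interpolated) integration over the ranking.
auprc_from_scores <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Macro-averaged per-query AUROC and AUPRC
#'
#' Scores are negated distances; each query's AUROC (concordant-pair rank
#' statistic) and AUPRC (step integration of the precision-recall curve) is
#' computed against its neighbor labels, then averaged over queries.
#' Degenerate queries (no positive or no negative among ranked entries) are
#' skipped with a warning.
#'
#' @inheritParams topk_hit_ratio
#' @return list `avg_auroc`, `avg_auprc`, `per_query` (data.frame),
#'   `n_queries`.
#' @export
per_query_roc_pr <- function(rankings, neighbors) {
  rows <- list()
  for (q in names(rankings)) {
    rk <- rankings[[q]]
    lab <- rk$ordered_ids %in% neighbors[[q]]
    if (!any(lab) || all(lab)) {
      warning("query '", q, "' is degenerate (all or no positives); skipped")
      next
    }
    sc <- -rk$distances
    rows[[q]] <- data.frame(query_id = q,
                            auroc = auroc_from_scores(sc, lab),
                            auprc = auprc_from_scores(sc, lab))
  }
  if (length(rows) == 0) stop("no evaluable query")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(avg_auroc = mean(per$auroc), avg_auprc = mean(per$auprc),
       per_query = per, n_queries = nrow(per))
}

#' Logistic-regression fold-class probe
#'
#' Stratified k-fold cross-validation of a multinomial logistic regression
#' on raw descriptors; reports pooled held-out accuracy and macro-averaged
#' F1. Classes with fewer members than `folds` reduce the fold count with a
#' warning.
#'
#' @param descriptors numeric matrix, one descriptor per row.
#' @param class_labels factor (or coercible) of matching length.
#' @param folds number of cross-validation folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return list `accuracy`, `macro_f1`, `per_class_f1`, `folds`.
#' @export
classification_probe <- function(descriptors, class_labels, folds = 10,
                                 seed = 1) {
  descriptors <- as.matrix(descriptors)
  y <- factor(class_labels)
  stopifnot(nrow(descriptors) == length(y))
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest class has ", min_class, " members; folds reduced")
    folds <- max(2L, min_class)
  }
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    members <- which(y == cl)
    fold_of[members] <- sample(rep_len(seq_len(folds), length(members)))
  }
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    df_train <- data.frame(y = y[!test], descriptors[!test, , drop = FALSE])
    fit <- nnet::multinom(y ~ ., data = df_train, trace = FALSE,
                          MaxNWts = 1e6, maxit = 200)
    pr <- stats::predict(fit,
                         newdata = data.frame(descriptors[test, , drop = FALSE]))
    pred[test] <- factor(as.character(pr), levels = levels(y))
  }
  conf <- table(truth = y, pred = pred)
  per_class_f1 <- vapply(levels(y), function(cl) {
    tp <- conf[cl, cl]
    prec <- if (sum(conf[, cl]) == 0) 0 else tp / sum(conf[, cl])
    rec <- if (sum(conf[cl, ]) == 0) 0 else tp / sum(conf[cl, ])
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(accuracy = mean(pred == y), macro_f1 = mean(per_class_f1),
       per_class_f1 = per_class_f1, folds = folds)
}

#' Half-resampling paired significance test between two methods
#'
#' Half of the queries are sampled without replacement `repeats` times; the
#' mean per-query metric of each method on each half-sample forms a paired
#' sample. If the paired differences pass a Shapiro-Wilk normality check
#' (alpha = 0.05) a paired t-test is used, otherwise the Wilcoxon
#' signed-rank test. All-zero differences are reported as "no difference"
#' with p = 1.
#'
#' @param metric_a,metric_b named per-query metric vectors (same queries).
#' @param repeats number of half-samples (default 10).
#' @param seed RNG seed.
#' @return list `statistic`, `p_value`, `test_name`, `means` (repeats x 2).
#' @export
significance_test <- function(metric_a, metric_b, repeats = 10, seed = 1) {
  stopifnot(identical(sort(names(metric_a)), sort(names(metric_b))))
  qids <- names(metric_a)
  if (length(qids) < 3) stop("need at least 3 queries")
  metric_b <- metric_b[qids]
  set.seed(seed)
  means <- matrix(0, repeats, 2, dimnames = list(NULL, c("a", "b")))
  for (r in seq_len(repeats)) {
    half <- sample(qids, ceiling(length(qids) / 2))
    means[r, ] <- c(mean(metric_a[half]), mean(metric_b[half]))
  }
  diffs <- means[, 1] - means[, 2]
  if (all(diffs == 0)) {
    return(list(statistic = 0, p_value = 1, test_name = "no difference",
                means = means))
  }
  normal <- tryCatch(stats::shapiro.test(diffs)$p.value >= 0.05,
                     error = function(e) FALSE)
  if (normal) {
    tt <- stats::t.test(means[, 1], means[, 2], paired = TRUE)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         test_name = "paired t-test", means = means)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(means[, 1], means[, 2],
                                              paired = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         test_name = "Wilcoxon signed-rank", means = means)
  }
}

#' Full ranking evaluation of a descriptor database
#'
#' Convenience wrapper: ranks every entry against the database, derives
#' neighbor sets from the similarity table, and reports macro AUROC/AUPRC
#' and Top-K hit ratios.
#'
#' @param db a [build_descriptor_db] result.
#' @param sim_table square named similarity matrix.
#' @param ks Top-K cutoffs (default `c(1, 5, 10)`).
#' @param rho neighbor threshold (default 0.9).
#' @return list `avg_auroc`, `avg_auprc`, `hit_ratio_at` (named), `per_query`,
#'   `n_queries`.
#' @export
evaluate_ranking <- function(db, sim_table, ks = c(1, 5, 10), rho = 0.9) {
  rankings <- rank_all(db)
  nbrs <- lapply(names(rankings), function(q) {
    others <- setdiff(colnames(sim_table), q)
    define_neighbors(sim_table[q, others], rho)$neighbor_ids
  })
  names(nbrs) <- names(rankings)
  rocpr <- per_query_roc_pr(rankings, nbrs)
  hits <- vapply(ks, function(k) topk_hit_ratio(rankings, nbrs, k), numeric(1))
  names(hits) <- paste0("K", ks)
  c(rocpr[c("avg_auroc", "avg_auprc")],
    list(hit_ratio_at = hits, per_query = rocpr$per_query,
         n_queries = rocpr$n_queries))
}
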