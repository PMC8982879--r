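# Neighbor definition, ranking metrics, classification probe, significance.

make_ranking <- function(q, ids) {
  structure(list(query_id = q, ordered_ids = ids,
                 distances = seq_along(ids)), class = "ranking_result")
}

test_that("structural neighbors follow the 0.9 x max rule", {
  s <- c(a = 0.9, b = 0.85, c = 0.3)
  nb <- define_neighbors(s, rho = 0.9)
  expect_setequal(nb$neighbor_ids, c("a", "b"))  # threshold 0.81
  expect_equal(nb$tm_max, 0.9)
  expect_setequal(define_neighbors(c(a = 0.5, b = 0.5))$neighbor_ids,
                  c("a", "b"))  # all equal -> all neighbors
  expect_equal(define_neighbors(s, rho = 1)$neighbor_ids, "a")
  expect_error(define_neighbors(numeric(0)), "empty")
})

test_that("Top-K hit ratio evaluates the normalized hit count", {
  nbrs <- list(q1 = c("a", "b", "c"))
  # all 3 neighbors in top 10 -> 1
  rk <- list(q1 = make_ranking("q1", c("a", "x", "b", "y", "c",
                                       paste0("z", 1:5))))
  expect_equal(topk_hit_ratio(rk, nbrs, 10), 1)
  # only 2 retrieved -> 2/3
  rk2 <- list(q1 = make_ranking("q1", c("a", "x", "b", paste0("z", 1:7),
                                        "c")))
  expect_equal(topk_hit_ratio(rk2, nbrs, 10), 2 / 3)
  # zero-neighbor query excluded with warning
  rk3 <- c(rk, list(q2 = make_ranking("q2", c("a", "b"))))
  expect_warning(v <- topk_hit_ratio(rk3, c(nbrs, list(q2 = character(0))),
                                     10), "no structural neighbors")
  expect_equal(v, 1)
})

test_that("Ratio_1 equals Top-1 accuracy on randomized instances", {
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(5:20, 1)
    ids <- sprintf("s%02d", 1:n)
    nq <- sample(3:6, 1)
    rankings <- list(); nbrs <- list()
    top1_hits <- 0
    for (qi in 1:nq) {
      q <- paste0("q", qi)
      perm <- sample(ids)
      rankings[[q]] <- make_ranking(q, perm)
      nbrs[[q]] <- sample(ids, sample(1:4, 1))
      top1_hits <- top1_hits + (perm[1] %in% nbrs[[q]])
    }
    expect_equal(topk_hit_ratio(rankings, nbrs, 1), top1_hits / nq)
  }
})

test_that("per-query AUROC/AUPRC: extremes and pair-counting oracle", {
  ids <- sprintf("s%02d", 1:100)
  nbrs <- list(q = ids[1:3])
  expect_equal(per_query_roc_pr(list(q = make_ranking("q", ids)), nbrs),
               list(avg_auroc = 1, avg_auprc = 1,
                    per_query = data.frame(query_id = "q", auroc = 1,
                                           auprc = 1),
                    n_queries = 1))
  # inverted ranking, single positive last -> AUROC 0
  inv <- list(q = make_ranking("q", c(ids[-1], ids[1])))
  expect_equal(per_query_roc_pr(inv, list(q = ids[1]))$avg_auroc, 0)
  # random queries vs O(P*N) concordant-pair oracle
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    idsr <- sprintf("r%02d", 1:n)
    perm <- sample(idsr)
    pos <- sample(idsr, sample(2:(n - 2), 1))
    res <- per_query_roc_pr(list(q = make_ranking("q", perm)),
                            list(q = pos))
    scores <- -seq_along(perm)
    lab <- perm %in% pos
    conc <- 0
    for (i in which(lab)) {
      for (j in which(!lab)) {
        conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
    }
    expect_equal(res$avg_auroc, conc / (sum(lab) * sum(!lab)),
                 tolerance = 1e-12)
  }
  # a degenerate query (all positives) is skipped; valid queries still score
  expect_warning(
    res_deg <- per_query_roc_pr(
      list(q = make_ranking("q", c("a", "b")),
           q2 = make_ranking("q2", c("a", "b"))),
      list(q = c("a", "b"), q2 = "a")),
    "degenerate")
  expect_equal(res_deg$n_queries, 1)
})

test_that("macro-AUROC of random rankings concentrates at 0.5", {
  set.seed(12)
  ids <- sprintf("s%03d", 1:60)
  nbrs <- lapply(1:40, function(i) sample(ids, 5))
  names(nbrs) <- paste0("q", 1:40)
  rankings <- lapply(names(nbrs), function(q) make_ranking(q, sample(ids)))
  names(rankings) <- names(nbrs)
  res <- per_query_roc_pr(rankings, nbrs)
  expect_lt(abs(res$avg_auroc - 0.5), 0.05)
})

test_that("classification probe separates margin-separated classes", {
  set.seed(13)
  n <- 40
  x <- rbind(matrix(rnorm(n * 5, mean = 2), n),
             matrix(rnorm(n * 5, mean = -2), n))
  y <- rep(c("up", "down"), each = n)
  res <- classification_probe(x, y, folds = 10, seed = 3)
  expect_gte(res$accuracy, 0.95)
  expect_gte(res$macro_f1, 0.95)
  # same seed -> identical report
  expect_identical(res, classification_probe(x, y, folds = 10, seed = 3))
  # shuffled labels -> chance-level macro F1
  yperm <- sample(y)
  resp <- classification_probe(x, yperm, folds = 10, seed = 3)
  expect_lt(abs(resp$macro_f1 - 0.5), 0.2)
  # small classes reduce the fold count
  expect_warning(r2 <- classification_probe(x[1:12, ], y[c(1:6, 41:46)],
                                            folds = 10, seed = 1),
                 "reduced")
  expect_lte(r2$folds, 6)
})

test_that("significance test: no-difference, separation, determinism", {
  set.seed(14)
  qs <- paste0("q", 1:20)
  a <- stats::setNames(runif(20), qs)
  same <- significance_test(a, a, seed = 5)
  expect_equal(same$p_value, 1)
  expect_equal(same$test_name, "no difference")
  # strong dominance -> significant
  b <- a - 0.3
  sep <- significance_test(a, b, seed = 5)
  expect_lt(sep$p_value, 0.05)
  # same seed -> same half-samples
  expect_identical(sep$means, significance_test(a, b, seed = 5)$means)
  expect_error(significance_test(a[1:2], a[1:2] * 0.5), "at least 3")
})
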