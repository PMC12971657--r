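test_that("confusion counts and accuracy follow the printed-form definitions", {
  # binary worked case: TP=3, TN=4, FP=1, FN=2 -> accuracy 0.7
  counts <- c(TP = 3, TN = 4, FP = 1, FN = 2)
  expect_equal((counts[["TP"]] + counts[["TN"]]) / sum(counts), 0.7)
  y_true <- c(rep(1, 5), rep(0, 5))          # 5 positives, 5 negatives
  y_pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)  # 3 TP, 2 FN, 1 FP, 4 TN
  cm <- confusion(y_true, y_pred, 2)
  expect_equal(cm$per_class$class1, counts)
  expect_equal(sum(diag(cm$matrix)) / length(y_true), 0.7)

  # perfect predictions
  cmp <- confusion(0:3, 0:3, 4)
  for (cl in cmp$per_class) expect_equal(cl[["FP"]] + cl[["FN"]], 0)

  # degenerate predictor: everything class 0
  cmd <- confusion(c(0, 1, 2, 3), c(0, 0, 0, 0), 4)
  expect_equal(prf1(cmd$per_class$class0)$recall, 1)
  for (k in 2:4) expect_equal(prf1(cmd$per_class[[k]])$recall, 0)
  expect_error(confusion(c(0, 5), c(0, 1), 4), "range")
})

test_that("precision/recall/F1 match the worked values and conventions", {
  r <- prf1(c(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(round(r$f1, 4), 0.6667)

  r0 <- prf1(c(TP = 0, TN = 5, FP = 0, FN = 2))
  expect_equal(r0$precision, 0)
  expect_true("precision" %in% r0$degenerate)

  # harmonic-mean fixed point and upper bound
  set.seed(601)
  for (i in 1:20) {
    tp <- sample(0:10, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    r <- prf1(c(TP = tp, TN = 1, FP = fp, FN = fn))
    if (r$precision == r$recall) expect_equal(r$f1, r$precision)
    expect_lte(r$f1, 2 * min(r$precision, r$recall) + 1e-12)
    expect_gte(r$f1, 0)
  }
})

test_that("rank AUC matches its closed forms and pairwise probability", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.4), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(c(0.9, 0.4, 0.8, 0.7), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(auc_rank(rep(0.3, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  expect_error(auc_rank(c(1, 2), c(TRUE, TRUE)), "negative")
  expect_error(auc_rank(c(1, 2), c(FALSE, FALSE)), "positive")
})

test_that("rank AUC equals pairwise and trapezoidal oracles on 200 instances", {
  set.seed(602)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    pos <- rep(FALSE, n)
    pos[sample(n, sample(2:(n - 2), 1))] <- TRUE
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    a <- auc_rank(scores, pos)
    expect_equal(a, oracle_auc_pairs(scores, pos), tolerance = 1e-9)
    expect_equal(a, oracle_auc_trapezoid(scores, pos), tolerance = 1e-9)
  }
})

test_that("rank AUC is invariant under strictly increasing transforms", {
  set.seed(603)
  scores <- runif(40)
  pos <- runif(40) > 0.5; pos[1] <- TRUE; pos[2] <- FALSE
  a <- auc_rank(scores, pos)
  expect_equal(auc_rank(exp(3 * scores), pos), a)
  expect_equal(auc_rank(rank(scores), pos), a)
  expect_equal(auc_rank(scores^3 + 10, pos), a)
})

test_that("rank AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(604)
  scores <- runif(60)
  pos <- runif(60) > 0.4
  a <- auc_rank(scores, pos)
  b <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                      quiet = TRUE, direction = "<")))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("evaluate_scores aggregates per-class metrics macro-style", {
  # one-hot perfect scores
  y <- rep(0:3, each = 5)
  sc <- matrix(0, 20, 4); sc[cbind(1:20, y + 1)] <- 1
  rep_ <- evaluate_scores(sc, y)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$macro$f1, 1)
  expect_equal(rep_$per_class$auc, rep(1, 4))

  # uniform scores with balanced labels: AUC 1/2 per class
  scu <- matrix(0.25, 20, 4)
  repu <- evaluate_scores(scu, y)
  expect_equal(repu$per_class$auc, rep(0.5, 4))

  # macro AUC is the unweighted mean of the per-class values
  set.seed(605)
  scr <- matrix(runif(80), 20, 4); scr <- scr / rowSums(scr)
  repr <- evaluate_scores(scr, y)
  expect_equal(repr$macro$auc, mean(repr$per_class$auc))
  expect_equal(repr$accuracy, sum(diag(repr$confusion)) / 20)
  expect_error(evaluate_scores(scr, y[1:10]), "length")
})

test_that("metrics reports are written as flat key/value plus ROC CSVs", {
  set.seed(606)
  y <- rep(0:3, each = 6)
  sc <- matrix(runif(96), 24, 4); sc <- sc / rowSums(sc)
  rep_ <- evaluate_scores(sc, y)
  d <- file.path(tempdir(), "metrep")
  write_metrics_report(rep_, d)
  lines <- readLines(file.path(d, "metrics.txt"))
  expect_true(any(grepl("^accuracy:", lines)))
  expect_true(any(grepl("^macro_f1:", lines)))
  roc <- utils::read.csv(file.path(d, "roc_class0.csv"))
  expect_named(roc, c("fpr", "tpr"))
  expect_equal(roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(as.numeric(roc[nrow(roc), ]), c(1, 1))
})
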