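test_that("confusion counts tally one-vs-rest outcomes", {
  perfect <- confusion_counts(c("a", "b", "c"), c("a", "b", "c"))
  expect_true(all(perfect$FP == 0) && all(perfect$FN == 0))

  cc <- confusion_counts(rep("B", 3), rep("A", 3), classes = c("A", "B"))
  expect_equal(cc$TP[cc$class == "A"], 0)
  expect_equal(cc$FN[cc$class == "A"], 3)
  expect_equal(cc$FP[cc$class == "B"], 3)

  # counts sum to n for every class
  set <- random_score_set(25, 4, seed = 61)
  preds <- as.character(max.col(set$scores))
  cc2 <- confusion_counts(preds, as.character(set$truth_idx),
                          classes = as.character(1:4))
  expect_true(all(cc2$TP + cc2$FP + cc2$FN + cc2$TN == 25))
  expect_error(confusion_counts("z", "a", classes = c("a", "b")), "universe")
})

test_that("precision/recall/F1 match the printed formulas with 0/0 -> 0", {
  tab <- prf1(data.frame(class = "k", TP = 8, FP = 2, FN = 2, TN = 20))
  expect_equal(tab$precision, 0.8)
  expect_equal(tab$recall, 0.8)
  expect_equal(tab$f1, 0.8)

  expect_warning(
    degenerate <- prf1(data.frame(class = "k", TP = 0, FP = 0, FN = 0,
                                  TN = 5)),
    "degenerate")
  expect_equal(degenerate$precision, 0)
  expect_equal(degenerate$recall, 0)
  expect_equal(degenerate$f1, 0)

  # F1 never exceeds either component
  for (k in 1:20) {
    cts <- withr::with_seed(k, as.list(sample(0:10, 3, replace = TRUE)))
    t2 <- suppressWarnings(
      prf1(data.frame(class = "x", TP = cts[[1]], FP = cts[[2]],
                      FN = cts[[3]], TN = 5)))
    expect_lte(t2$f1, max(t2$precision, t2$recall) + 1e-12)
  }
})

test_that("top-5 accuracy ranks with deterministic tie-breaks", {
  # truth always ranked 3rd: top-1 fails, top-5 succeeds
  s <- matrix(rep(c(0.3, 0.25, 0.2, 0.1, 0.08, 0.07), 4), 4, byrow = TRUE)
  truth <- rep("3", 4)
  colnames(s) <- as.character(1:6)
  expect_equal(accuracy(as.character(max.col(s)), truth), 0)
  expect_equal(top5_accuracy(s, truth), 1)

  set <- random_score_set(20, 8, seed = 62)
  expect_equal(top5_accuracy(set$scores, as.character(set$truth_idx),
                             classes = as.character(1:8)),
               oracle_top_k(set$scores, set$truth_idx, 5))
  expect_error(top5_accuracy(set$scores[, 1:4], "1",
                             classes = as.character(1:4)), "at least")
})

test_that("pairwise AUC matches the double sum and the ROC area", {
  # perfect separation
  expect_equal(auc_pairwise(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # identical scores: 0.5 under the tie convention, 0 under the strict one
  expect_equal(auc_pairwise(rep(0.4, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE,
                                           FALSE)), 0.5)
  expect_equal(auc_pairwise(rep(0.4, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE,
                                           FALSE), strict = TRUE), 0)

  for (k in 1:15) {
    n <- 30
    sc <- withr::with_seed(k, round(stats::runif(n), 2))  # induces ties
    pos <- withr::with_seed(k + 99, stats::runif(n) > 0.5)
    if (!any(pos) || all(pos)) next
    expect_equal(auc_pairwise(sc, pos), oracle_auc(sc, pos),
                 tolerance = 1e-12)
    curve <- roc_curve(sc, pos)
    expect_lt(abs(birdcall:::roc_auc(curve) - auc_pairwise(sc, pos)), 1e-10)
  }
  expect_error(auc_pairwise(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("ROC curves are monotone staircases with fixed endpoints", {
  sc <- withr::with_seed(70, stats::runif(40))
  pos <- withr::with_seed(71, stats::runif(40) > 0.6)
  cv <- roc_curve(sc, pos)
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(utils::tail(cv$fpr, 1), 1)
  expect_equal(utils::tail(cv$tpr, 1), 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))

  perfect <- roc_curve(c(0.1, 0.2, 0.8, 0.9),
                       c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
})

test_that("average precision reproduces the staircase sum", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1),
                                 c(TRUE, TRUE, FALSE, FALSE)), 1)
  # the worked four-sample case: AP = 1 * 1/2 + (2/3) * 1/2 = 5/6
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6),
                                 c(TRUE, FALSE, TRUE, FALSE)), 5 / 6,
               tolerance = 1e-12)
  for (k in 1:15) {
    sc <- withr::with_seed(k + 300, stats::runif(25))
    pos <- withr::with_seed(k + 400, stats::runif(25) > 0.6)
    if (!any(pos)) next
    expect_equal(average_precision(sc, pos), oracle_ap(sc, pos),
                 tolerance = 1e-12)
  }
  expect_error(average_precision(1:3, rep(FALSE, 3)), "positive")
})

test_that("mAP is the unweighted mean of per-class APs", {
  set <- random_score_set(30, 2, seed = 80)
  truths <- as.character(set$truth_idx)
  colnames(set$scores) <- c("1", "2")
  ap1 <- average_precision(set$scores[, 1], truths == "1")
  ap2 <- average_precision(set$scores[, 2], truths == "2")
  expect_equal(map_score(set$scores, truths), mean(c(ap1, ap2)),
               tolerance = 1e-12)
})

test_that("every metric agrees with brute force on random small score sets", {
  for (k in 1:50) {
    n <- withr::with_seed(k, sample(8:30, 1))
    K <- withr::with_seed(k + 1000, sample(2:6, 1))
    set <- random_score_set(n, K, seed = k + 2000)
    truths <- as.character(set$truth_idx)
    classes <- as.character(seq_len(K))
    if (length(unique(truths)) < 2) next
    scores <- set$scores; colnames(scores) <- classes
    preds <- classes[max.col(scores, "first")]

    expect_equal(accuracy(preds, truths), oracle_accuracy(preds, truths),
                 tolerance = 1e-12)
    ref_prf <- oracle_prf1(preds, truths, classes)
    got <- suppressWarnings(prf1(confusion_counts(preds, truths, classes)))
    for (ci in seq_len(K)) {
      expect_lt(max(abs(unlist(got[ci, c("precision", "recall", "f1")]) -
                          ref_prf[[classes[ci]]])), 1e-10)
    }
    for (ci in seq_len(K)) {
      pos <- truths == classes[ci]
      if (!any(pos) || all(pos)) next
      expect_lt(abs(auc_pairwise(scores[, ci], pos) -
                      oracle_auc(scores[, ci], pos)), 1e-10)
      expect_lt(abs(average_precision(scores[, ci], pos) -
                      oracle_ap(scores[, ci], pos)), 1e-10)
    }
    if (K >= 5) {
      expect_equal(top5_accuracy(scores, truths, classes = classes),
                   oracle_top_k(scores, set$truth_idx, 5), tolerance = 1e-12)
    }
  }
})

test_that("micro and macro AUC/ROC aggregate one-vs-rest views", {
  set <- random_score_set(40, 4, seed = 83)
  truths <- as.character(set$truth_idx)
  classes <- as.character(1:4)
  colnames(set$scores) <- classes
  auc <- auc_multiclass(set$scores, truths, classes)
  expect_equal(auc$macro, mean(auc$per_class), tolerance = 1e-12)
  # micro AUC equals the pairwise AUC over the pooled one-vs-rest pairs
  pooled_pos <- as.vector(vapply(classes, function(k) truths == k,
                                 logical(40)))
  expect_equal(auc$micro, auc_pairwise(as.vector(set$scores), pooled_pos),
               tolerance = 1e-12)
  rocs <- roc_multiclass(set$scores, truths, classes)
  expect_length(rocs$per_class, 4)
  expect_lt(abs(birdcall:::roc_auc(rocs$micro) - auc$micro), 1e-10)
  # macro curve is a proper averaged curve on the FPR grid
  expect_equal(range(rocs$macro$fpr), c(0, 1))
  expect_true(all(rocs$macro$tpr >= 0 & rocs$macro$tpr <= 1))
  # a class with no positives is skipped with a warning
  expect_warning(auc_multiclass(set$scores, ifelse(truths == "4", "1",
                                                   truths), classes),
                 "skipped")
})

test_that("PCA embedding projects onto the top variance axes", {
  # collinear points: second component carries (almost) no variance
  line <- cbind(1:20, 2 * (1:20) + 3, -0.5 * (1:20))
  emb <- pca_embed(line)
  expect_equal(dim(emb), c(20, 2))
  expect_lt(stats::var(emb[, 2]), 1e-20)

  x <- withr::with_seed(90, matrix(stats::rnorm(600 * 50), 600, 50))
  emb600 <- pca_embed(x)
  expect_equal(dim(emb600), c(600, 2))
  expect_gte(stats::var(emb600[, 1]), stats::var(emb600[, 2]))

  # matches a brute-force eigendecomposition up to sign
  xs <- withr::with_seed(91, matrix(stats::rnorm(40 * 6), 40, 6))
  ev <- eigen(stats::cov(xs))$vectors[, 1:2]
  ref <- scale(xs, scale = FALSE) %*% ev
  got <- pca_embed(xs)
  for (j in 1:2) {
    expect_lt(min(max(abs(got[, j] - ref[, j])),
                  max(abs(got[, j] + ref[, j]))), 1e-8)
  }
  expect_error(pca_embed(matrix(1:4, 2, 2)), "samples")
})

test_that("the assembled report behaves on oracle and random scorers", {
  # oracle scorer: reads the label
  truths <- rep(c("a", "b", "c"), each = 5)
  scores <- birdcall:::one_hot(as.integer(factor(truths)), 3) * 0.94 + 0.02
  colnames(scores) <- c("a", "b", "c")
  rep1 <- evaluate_scores(scores, truths)
  expect_equal(rep1$summary$accuracy, 1)
  expect_equal(rep1$summary$f1, 1)
  expect_equal(rep1$summary$map, 1)

  # uniform-random scores over 8 balanced classes: accuracy near 1/8
  n <- 400
  set <- random_score_set(n, 8, seed = 95)
  truths8 <- as.character(rep(1:8, each = 50))
  rep2 <- evaluate_scores(set$scores, truths8, classes = as.character(1:8))
  se <- sqrt((1 / 8) * (7 / 8) / n)
  expect_lt(abs(rep2$summary$accuracy - 1 / 8), 3 * se)
  rates <- unlist(rep2$summary)
  expect_true(all(rates >= 0 & rates <= 1))
  expect_gte(rep2$summary$top5_accuracy, rep2$summary$accuracy)

  expect_error(evaluate_scores(set$scores[0, , drop = FALSE], character(0)),
               "empty")

  # report serialization
  dir <- tempfile("report_")
  write_report(rep2, dir)
  expect_true(file.exists(file.path(dir, "per_class.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$accuracy, rep2$summary$accuracy, tolerance = 1e-12)
})
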