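test_that("confusion counts partition instances with >= threshold positive", {
  cc <- confusion_counts(c(0.9, 0.2), c(1, 0))
  expect_equal(cc, c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # boundary score 0.5 predicts positive
  cc2 <- confusion_counts(c(0.5), c(0))
  expect_equal(cc2[["FP"]], 1L)
  cc3 <- confusion_counts(rep(0, 5), rep(1, 5))
  expect_equal(cc3, c(TP = 0L, TN = 0L, FP = 0L, FN = 5L))
  expect_error(confusion_counts(c(0.1), c(1, 0)), "equal length")
})

test_that("classification metrics follow the standard formulas", {
  m <- classification_metrics(3, 2, 1, 0)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 6 / 7)
  expect_length(m$undefined, 0L)
  # zero-denominator convention: flagged zero, not NaN
  m2 <- classification_metrics(0, 5, 0, 2)
  expect_equal(m2$precision, 0)
  expect_true("precision" %in% m2$undefined)
  perfect <- classification_metrics(4, 4, 0, 0)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
})

test_that("f1 is the harmonic mean of precision and recall when defined", {
  set.seed(1)
  for (i in 1:25) {
    cc <- as.list(sample(0:10, 4, replace = TRUE))
    names(cc) <- c("tp", "tn", "fp", "fn")
    if (sum(unlist(cc)) == 0) next
    m <- do.call(classification_metrics, cc)
    expect_equal(m$accuracy, (cc$tp + cc$tn) / sum(unlist(cc)))
    if (!length(m$undefined) && (m$precision + m$recall) > 0) {
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
    }
  }
})

test_that("trapezoidal AUC matches hand-checked cases and handles ties", {
  # perfectly separated
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # 3 of 4 positive-negative pairs concordant
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  # all scores identical: tie convention gives 0.5
  expect_equal(roc_auc(rep(0.7, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("ROC points start at (0,0), end at (1,1), FPR non-decreasing", {
  set.seed(2)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  roc <- roc_auc(scores, labels)$roc_points
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("trapezoidal AUC equals Mann-Whitney concordance on random sets", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(6:40, 1L)
    # discretized scores force plenty of ties
    scores <- round(runif(n), sample(c(1L, 2L), 1L))
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
    expect_equal(roc_auc(scores, labels)$auc,
                 mann_whitney_auc(scores, labels), tolerance = 1e-9)
  }
})

test_that("metrics are invariant under instance permutation", {
  set.seed(4)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  perm <- sample(30)
  a <- metrics_report(scores, labels)
  b <- metrics_report(scores[perm], labels[perm])
  for (k in c("TP", "TN", "FP", "FN", "accuracy", "precision", "recall",
              "f1", "auc")) {
    expect_equal(a[[k]], b[[k]])
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- round(runif(60), 2)
  labels <- rbinom(60, 1, 0.4)
  labels[1:2] <- c(0, 1)
  ours <- roc_auc(scores, labels)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("metric reports serialize to JSON", {
  rep_ <- metrics_report(c(0.9, 0.4, 0.8, 0.1), c(1, 0, 1, 0))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_metrics_json(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep_$accuracy)
  expect_equal(back$auc, rep_$auc)
})

test_that("the sparse classifier beats size-matched random selection", {
  cohort <- tiny_cohort(seed = 6)
  rv <- rescale_unit(cohort$rna)$values
  mv <- rescale_unit(cohort$meth)$values
  rl <- stats::setNames(cohort$rna$labels, rownames(cohort$rna$values))
  ml <- stats::setNames(cohort$meth$labels, rownames(cohort$meth$values))
  sp_r <- stratified_split(cohort$rna, 0.3, 1)
  sp_m <- stratified_split(cohort$meth, 0.3, 2)
  train_plan <- omixfuse:::make_eval_plan(sp_r$train, sp_m$train, rl, ml)
  test_plan <- omixfuse:::make_eval_plan(sp_r$test, sp_m$test, rl, ml)
  # oracle ranking puts the truly informative features first
  truth_feats <- rbind(
    data.frame(feature_id = cohort$truth$informative_rna, modality = "rna"),
    data.frame(feature_id = cohort$truth$informative_meth,
               modality = "meth"))
  rest <- rbind(
    data.frame(feature_id = setdiff(colnames(rv),
                                    cohort$truth$informative_rna),
               modality = "rna"),
    data.frame(feature_id = setdiff(colnames(mv),
                                    cohort$truth$informative_meth),
               modality = "meth"))
  ranking <- rbind(truth_feats, rest)
  ranking$rank <- seq_len(nrow(ranking))
  res <- feature_subset_classifier(rv, mv, ranking, train_plan, test_plan,
                                   k = 16L, seed = 3)
  expect_gte(res$attributed$auc, res$random$auc)
  expect_gt(res$attributed$auc, 0.8)
  expect_named(res, c("attributed", "random", "variance", "f_score", "pca"))
  expect_error(feature_subset_classifier(rv, mv, ranking, train_plan,
                                         test_plan, k = 1e5), "exceeds")
})

test_that("k = 1 on the dominant informative feature still carries signal", {
  cohort <- tiny_cohort(seed = 8)
  rv <- rescale_unit(cohort$rna)$values
  mv <- rescale_unit(cohort$meth)$values
  rl <- stats::setNames(cohort$rna$labels, rownames(cohort$rna$values))
  ml <- stats::setNames(cohort$meth$labels, rownames(cohort$meth$values))
  sp_r <- stratified_split(cohort$rna, 0.3, 3)
  sp_m <- stratified_split(cohort$meth, 0.3, 4)
  ranking <- data.frame(feature_id = cohort$truth$informative_rna[1],
                        modality = "rna", rank = 1L)
  res <- feature_subset_classifier(
    rv, mv, ranking,
    omixfuse:::make_eval_plan(sp_r$train, sp_m$train, rl, ml),
    omixfuse:::make_eval_plan(sp_r$test, sp_m$test, rl, ml),
    k = 1L, comparators = FALSE)
  expect_gt(res$attributed$auc, 0.5)
})

test_that("modality ablation tabulates all three conditions", {
  cohort <- tiny_cohort(seed = 11)
  pp <- intersect_features(cohort$rna, cohort$meth)
  tab <- modality_ablation(
    pp$rna, pp$meth,
    arch = tiny_arch(ncol(pp$rna$values), ncol(pp$meth$values)),
    cfg = train_config(max_epochs = 3L, early_stop_patience = 3L,
                       rna_per_batch = 16L, seed = 2))
  expect_equal(tab$condition, c("both", "rna", "meth"))
  expect_true(all(c("accuracy", "precision", "recall", "f1", "auc",
                    "accuracy_sample", "auc_sample") %in% colnames(tab)))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  runs <- attr(tab, "runs")
  expect_equal(runs$rna$modality, "rna")
})
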