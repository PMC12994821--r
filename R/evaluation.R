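# Classification metrics: confusion counts at a fixed threshold,
# accuracy/precision/recall/F1, and the trapezoidal ROC AUC over a
# threshold sweep with ties grouped.

#' Confusion counts at a probability threshold
#'
#' A score greater than or equal to `threshold` predicts the positive
#' class (the boundary counts as positive).
#'
#' @param scores Predicted probabilities in \[0, 1\].
#' @param labels Binary 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Named vector with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  pred <- scores >= threshold
  c(TP = sum(pred & labels == 1L), TN = sum(!pred & labels == 0L),
    FP = sum(pred & labels == 0L), FN = sum(!pred & labels == 1L))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Ratios with a zero denominator are reported as 0 and flagged in the
#' `undefined` attribute rather than returned as `NaN`, so downstream
#' tabulation never fails.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return A list with `accuracy`, `precision`, `recall`, `f1` and a
#'   character vector `undefined` naming any flagged-zero metrics.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  if (n == 0L) stop("all confusion counts are zero")
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f1 = f1, undefined = undefined)
}

#' Trapezoidal ROC AUC over a threshold sweep
#'
#' Thresholds sweep the unique scores (equal scores grouped into one
#' step); the curve starts at (0, 0), ends at (1, 1), and the AUC is the
#' trapezoidal sum over consecutive (FPR, TPR) points — equal to the
#' Mann-Whitney concordance probability with ties counted as one half.
#'
#' @param scores Predicted scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return A list with `auc` and the ordered `roc_points` data frame
#'   (`fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group ties: indices where a threshold step ends
  step_end <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(l == 1L)[step_end]
  fp <- cumsum(l == 0L)[step_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr))
}

#' Full metrics report for scored instances
#'
#' @param scores Predicted probabilities.
#' @param labels Binary 0/1 labels.
#' @param threshold Decision threshold for the confusion counts.
#' @return A `metrics_report` list: confusion counts, accuracy,
#'   precision, recall, F1, AUC, the ROC point set and the threshold.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_counts(scores, labels, threshold)
  cm <- classification_metrics(cc[["TP"]], cc[["TN"]], cc[["FP"]], cc[["FN"]])
  roc <- if (length(unique(labels)) == 2L) roc_auc(scores, labels)
         else list(auc = NA_real_, roc_points = NULL)
  structure(c(as.list(cc), cm[c("accuracy", "precision", "recall", "f1")],
              list(undefined = cm$undefined, auc = roc$auc,
                   roc_points = roc$roc_points, threshold = threshold,
                   n = length(scores))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report: n=%d acc=%.4f prec=%.4f rec=%.4f f1=%.4f auc=%.4f>\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Write a metrics report as JSON
#' @param report A `metrics_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  out <- unclass(report)
  out$roc_points <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Modality-ablation comparison
#'
#' Trains the model under identical seeds and configuration in three
#' conditions — fused, expression-only and methylation-only (the withheld
#' channel is fed a zero placeholder and its reconstruction losses are
#' dropped, keeping parameter counts comparable) — and tabulates held-out
#' test metrics.
#'
#' @param rna,meth Gene-level [omics_matrix] cohorts.
#' @param arch Optional [arch_config()].
#' @param cfg A [train_config()].
#' @param conditions Subset of `c("both", "rna", "meth")` to run.
#' @return A data frame with one row per condition: per-pair metric
#'   columns plus the sample-level `accuracy_sample` / `auc_sample`
#'   (each anchor sample scored by its mean predicted probability over
#'   its test pairs, which is the view comparable across conditions).
#'   Fitted runs are attached in the `runs` attribute.
#' @export
modality_ablation <- function(rna, meth, arch = NULL, cfg = train_config(),
                              conditions = c("both", "rna", "meth")) {
  runs <- lapply(conditions, function(cond) {
    fit_unpaired(rna, meth, arch = arch, cfg = cfg, modality = cond)
  })
  names(runs) <- conditions
  tab <- do.call(rbind, lapply(conditions, function(cond) {
    m <- runs[[cond]]$metrics
    ms <- runs[[cond]]$metrics_sample
    data.frame(condition = cond, accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               auc = m$auc, accuracy_sample = ms$accuracy,
               auc_sample = ms$auc)
  }))
  attr(tab, "runs") <- runs
  tab
}

# Per-feature one-way F statistic (squared two-sample t) for the
# univariate comparator ranking.
f_score_ranking <- function(x, y) {
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  v1 <- apply(x[y == 1L, , drop = FALSE], 2L, stats::var)
  v0 <- apply(x[y == 0L, , drop = FALSE], 2L, stats::var)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  (mu1 - mu0)^2 / (v1 / n1 + v0 / n0 + 1e-12)
}

#' Sparse re-classification on top-ranked features
#'
#' Trains an L2-regularized logistic model on the top-`k` attributed
#' features (the selected expression and methylation columns of each
#' pair concatenated) and evaluates it on held-out pairs. Optional
#' comparators select `k` features at random, by variance, by univariate
#' F score, or project onto the top `k` principal components, under the
#' same backbone.
#'
#' @param rna_vals,meth_vals Scaled value matrices (rows named by sample
#'   ID).
#' @param ranking Data frame from [aggregate_and_rank()] with columns
#'   `feature_id`, `modality`, `rank`.
#' @param train_plan,test_plan Pairing plans for training and evaluation.
#' @param k Number of features to keep (default 200).
#' @param comparators Also fit the comparator selections?
#' @param seed Seed for the random-selection comparator.
#' @return A list of [metrics_report()]s, one per selection method
#'   (`attributed` plus any comparators).
#' @export
feature_subset_classifier <- function(rna_vals, meth_vals, ranking,
                                      train_plan, test_plan, k = 200L,
                                      comparators = TRUE, seed = 1L) {
  if (k > nrow(ranking)) stop("k exceeds the number of ranked features")
  design <- function(plan) {
    cbind(rna_vals[plan$rna_id, , drop = FALSE],
          meth_vals[plan$meth_id, , drop = FALSE])
  }
  # Column index into the concatenated [rna | meth] design.
  col_index <- function(feature_id, modality) {
    j <- match(feature_id, colnames(rna_vals))
    ifelse(modality == "rna", j, ncol(rna_vals) + j)
  }
  xtr <- design(train_plan)
  xte <- design(test_plan)
  ytr <- train_plan$label
  yte <- test_plan$label
  fit_on <- function(cols = NULL, proj = NULL, center = NULL) {
    a <- if (!is.null(proj)) sweep(xtr, 2L, center) %*% proj
         else xtr[, cols, drop = FALSE]
    b <- if (!is.null(proj)) sweep(xte, 2L, center) %*% proj
         else xte[, cols, drop = FALSE]
    if (ncol(a) >= 2L) {
      fit <- glmnet::glmnet(a, ytr, family = "binomial", alpha = 0,
                            lambda = 1e-2, standardize = TRUE)
      sc <- as.numeric(stats::predict(fit, b, type = "response"))
    } else {
      df_tr <- data.frame(y = ytr, x = a[, 1L])
      fit <- stats::glm(y ~ x, data = df_tr, family = stats::binomial())
      sc <- as.numeric(stats::predict(fit, data.frame(x = b[, 1L]),
                                      type = "response"))
    }
    metrics_report(sc, yte)
  }
  ranking <- ranking[order(ranking$rank), , drop = FALSE]
  top <- ranking[seq_len(k), , drop = FALSE]
  out <- list(attributed = fit_on(col_index(top$feature_id, top$modality)))
  if (comparators) {
    all_cols <- seq_len(ncol(xtr))
    out$random <- with_seed(seed, fit_on(sample(all_cols, k)))
    vars <- apply(xtr, 2L, stats::var)
    out$variance <- fit_on(order(vars, decreasing = TRUE)[seq_len(k)])
    fs <- f_score_ranking(xtr, ytr)
    out$f_score <- fit_on(order(fs, decreasing = TRUE)[seq_len(k)])
    pc <- stats::prcomp(xtr, center = TRUE, scale. = FALSE,
                        rank. = min(k, nrow(xtr) - 1L, ncol(xtr)))
    out$pca <- fit_on(proj = pc$rotation, center = pc$center)
  }
  out
}
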