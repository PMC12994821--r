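# Counterfactual integrated-gradients attribution. Each feature's score
# is the path integral of the model-output gradient along the straight
# line from a reference baseline x' (all-zeros by default, representing
# "feature absent") to the input x, scaled by (x_i - x'_i) and
# approximated by the right-endpoint Riemann sum over n steps. The scores
# satisfy the completeness identity: their sum approaches
# F(x) - F(x') as the number of steps grows.

#' Integrated gradients for an arbitrary differentiable function
#'
#' Quadrature core shared by the model-specific attribution: given a
#' callback evaluating the function and its gradient on a batch of
#' inputs (rows), integrates the gradient along the straight-line path
#' from `baseline` to `x`.
#'
#' @param fgrad Function taking an inputs matrix (one path point per
#'   row) and returning `list(f = <vector>, grad = <matrix>)`.
#' @param x Numeric input vector.
#' @param baseline Numeric baseline vector of the same length.
#' @param n_steps Number of integration steps (>= 1).
#' @param rule `"trapezoid"` (default) or `"right"` (the plain
#'   right-endpoint Riemann sum of the discrete formula).
#' @return A list with per-feature `scores`, `f_x`, `f_baseline` and the
#'   absolute/relative `completeness_gap`.
#' @export
integrated_gradients_fn <- function(fgrad, x, baseline, n_steps = 64L,
                                    rule = c("trapezoid", "right")) {
  rule <- match.arg(rule)
  if (n_steps < 1L) stop("n_steps must be at least 1")
  if (length(baseline) != length(x))
    stop("custom baseline dimension does not match the input")
  if (rule == "right") {
    alpha <- seq_len(n_steps) / n_steps
    wts <- rep(1 / n_steps, n_steps)
  } else {
    alpha <- seq(0L, n_steps) / n_steps
    wts <- c(0.5, rep(1, n_steps - 1L), 0.5) / n_steps
  }
  path <- outer(1 - alpha, baseline) + outer(alpha, x)
  ev <- fgrad(path)
  scores <- (x - baseline) * as.numeric(crossprod(ev$grad, wts))
  f_x <- ev$f[length(alpha)]
  f_b <- if (rule == "trapezoid") ev$f[1L]
         else fgrad(matrix(baseline, nrow = 1L))$f[1L]
  gap <- abs(sum(scores) - (f_x - f_b))
  list(scores = scores, f_x = f_x, f_baseline = f_b,
       completeness_gap = gap,
       completeness_gap_rel = gap / max(abs(f_x - f_b), 1e-12))
}

resolve_baseline <- function(baseline, template) {
  if (is.numeric(baseline)) {
    if (length(baseline) != length(template))
      stop("custom baseline dimension does not match the input")
    return(baseline)
  }
  switch(match.arg(baseline, c("zeros", "ones")),
         zeros = rep(0, length(template)),
         ones = rep(1, length(template)))
}

#' Integrated gradients for one paired input
#'
#' Computes, for every expression and methylation feature,
#' `(x_i - x'_i)` times the average gradient of the model's
#' class-probability output `F` along the straight-line path
#' `g(k) = (1-k) x' + k x`. With `rule = "right"` the average is the
#' right-endpoint Riemann sum over `j/n`, `j = 1..n`, exactly as the
#' discrete summation is usually written; the default
#' `rule = "trapezoid"` weights the `n + 1` points `j/n`, `j = 0..n`,
#' with trapezoidal weights, whose O(1/n^2) quadrature error keeps the
#' completeness identity tight at moderate `n`. All path points are
#' evaluated in one batched forward/backward pass.
#'
#' @param model A trained `omixfuse_model`.
#' @param x_rna,x_meth Numeric input vectors (one sample each, scaled as
#'   the model expects).
#' @param baseline `"zeros"`, `"ones"`, or a list with numeric `rna` and
#'   `meth` vectors.
#' @param n_steps Number of integration steps (>= 1).
#' @param rule Quadrature rule along the path.
#' @return A list with per-feature `rna` and `meth` scores, the model
#'   outputs `f_x` and `f_baseline`, and the absolute and relative
#'   `completeness_gap`.
#' @export
integrated_gradients <- function(model, x_rna, x_meth, baseline = "zeros",
                                 n_steps = 64L,
                                 rule = c("trapezoid", "right")) {
  rule <- match.arg(rule)
  if (n_steps < 1L) stop("n_steps must be at least 1")
  x_rna <- as.numeric(x_rna)
  x_meth <- as.numeric(x_meth)
  if (is.list(baseline)) {
    b_rna <- resolve_baseline(baseline$rna, x_rna)
    b_meth <- resolve_baseline(baseline$meth, x_meth)
  } else {
    b_rna <- resolve_baseline(baseline, x_rna)
    b_meth <- resolve_baseline(baseline, x_meth)
  }
  p_rna <- length(x_rna)
  # One batched forward/backward per call: rows are independent, so
  # summing F over the path rows yields every row's own input gradient
  # in a single backward sweep.
  fgrad <- function(pts) {
    fw <- model_forward(model, pts[, seq_len(p_rna), drop = FALSE],
                        pts[, -seq_len(p_rna), drop = FALSE],
                        training = FALSE, input_grad = TRUE)
    tg_backward(tg_sum(fw$prob))
    list(f = as.numeric(tg_val(fw$prob)),
         grad = cbind(fw$x_rna$grad, fw$x_meth$grad))
  }
  out <- integrated_gradients_fn(fgrad, c(x_rna, x_meth),
                                 c(b_rna, b_meth), n_steps = n_steps,
                                 rule = rule)
  list(rna = out$scores[seq_len(p_rna)],
       meth = out$scores[-seq_len(p_rna)],
       f_x = out$f_x, f_baseline = out$f_baseline,
       completeness_gap = out$completeness_gap,
       completeness_gap_rel = out$completeness_gap_rel)
}

#' Attribute a set of samples (pairs) with integrated gradients
#'
#' @param model A trained `omixfuse_model`.
#' @param rna_vals,meth_vals Scaled value matrices (rows named by sample
#'   ID).
#' @param plan A `pairing_plan` naming which (expression, methylation)
#'   rows to attribute.
#' @param baseline,n_steps,rule Passed to [integrated_gradients()].
#' @return A list with score matrices `rna` and `meth` (samples x
#'   features) and the per-sample completeness gaps.
#' @export
attribute_pairs <- function(model, rna_vals, meth_vals, plan,
                            baseline = "zeros", n_steps = 64L,
                            rule = c("trapezoid", "right")) {
  n <- nrow(plan)
  if (n == 0L) stop("empty pairing plan")
  sc_rna <- matrix(0, n, ncol(rna_vals), dimnames = list(NULL,
                                                         colnames(rna_vals)))
  sc_meth <- matrix(0, n, ncol(meth_vals),
                    dimnames = list(NULL, colnames(meth_vals)))
  gaps <- numeric(n)
  for (i in seq_len(n)) {
    ig <- integrated_gradients(model, rna_vals[plan$rna_id[i], ],
                               meth_vals[plan$meth_id[i], ],
                               baseline = baseline, n_steps = n_steps,
                               rule = rule)
    sc_rna[i, ] <- ig$rna
    sc_meth[i, ] <- ig$meth
    gaps[i] <- ig$completeness_gap_rel
  }
  list(rna = sc_rna, meth = sc_meth, completeness_gap_rel = gaps)
}

#' Cross-validation-averaged attribution ranking
#'
#' Attributes held-out validation pairs with each fold's trained model
#' and averages the per-feature mean-absolute scores across folds. Fold
#' averaging stabilizes the ranking: correlated informative features are
#' interchangeable to any single model, so different folds spread their
#' attribution over different members of the correlated set and the
#' average covers their union.
#'
#' @param cv A [cross_validate()] result (fold models retained).
#' @param rna,meth The cohorts the cross-validation was run on.
#' @param n_pairs Validation pairs attributed per fold.
#' @param n_steps,baseline Passed to [integrated_gradients()].
#' @param seed Seed for drawing the attributed pairs.
#' @return A ranking data frame as from [aggregate_and_rank()].
#' @export
attribute_cv <- function(cv, rna, meth, n_pairs = 12L, n_steps = 64L,
                         baseline = "zeros", seed = 1L) {
  rl <- stats::setNames(rna$labels, rownames(rna$values))
  ml <- stats::setNames(meth$labels, rownames(meth$values))
  agg_rna <- 0
  agg_meth <- 0
  for (fr in cv$folds) {
    plan <- make_eval_plan(fr$val_ids$rna, fr$val_ids$meth, rl, ml, "both")
    idx <- with_seed(derive_seed(seed, paste0("attr_fold", fr$fold)),
                     sample(nrow(plan), min(n_pairs, nrow(plan))))
    sc_dat <- scale_cohorts(
      rna, meth,
      list(rna = setdiff(rownames(rna$values), fr$val_ids$rna),
           meth = setdiff(rownames(meth$values), fr$val_ids$meth)))
    sc <- attribute_pairs(fr$model, sc_dat$rna_vals, sc_dat$meth_vals,
                          plan[idx, , drop = FALSE], baseline = baseline,
                          n_steps = n_steps)
    agg_rna <- agg_rna + colMeans(abs(sc$rna))
    agg_meth <- agg_meth + colMeans(abs(sc$meth))
  }
  df <- rbind(
    data.frame(feature_id = colnames(rna$values), modality = "rna",
               score = agg_rna / length(cv$folds),
               stringsAsFactors = FALSE),
    data.frame(feature_id = colnames(meth$values), modality = "meth",
               score = agg_meth / length(cv$folds),
               stringsAsFactors = FALSE)
  )
  df <- df[order(df$score, decreasing = TRUE), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

# Mean-normalized average of per-feature score vectors from several
# models. Each vector is scaled to unit mean before averaging so that
# models with different output sensitivities contribute equally; used to
# build ensemble rankings over models trained under different
# conditions.
ensemble_scores <- function(score_vectors) {
  stopifnot(length(score_vectors) > 0L)
  total <- 0
  for (v in score_vectors) total <- total + v / max(mean(v), 1e-12)
  total / length(score_vectors)
}

#' Aggregate per-sample attribution scores and rank features
#'
#' Aggregates each feature's per-sample scores with the unweighted mean
#' of absolute values (default) or the signed mean, and ranks features of
#' both modalities jointly in descending aggregated order.
#'
#' @param scores A list with `rna` and `meth` score matrices (samples x
#'   features), as returned by [attribute_pairs()].
#' @param aggregation `"mean_absolute"` or `"signed_mean"`.
#' @return A data frame with `feature_id`, `modality`, `score` and
#'   `rank` (1 = most important).
#' @export
aggregate_and_rank <- function(scores,
                               aggregation = c("mean_absolute",
                                               "signed_mean")) {
  aggregation <- match.arg(aggregation)
  if (nrow(scores$rna) == 0L) stop("no attributed samples")
  agg <- function(m) {
    if (aggregation == "mean_absolute") colMeans(abs(m)) else colMeans(m)
  }
  df <- rbind(
    data.frame(feature_id = colnames(scores$rna), modality = "rna",
               score = agg(scores$rna), stringsAsFactors = FALSE),
    data.frame(feature_id = colnames(scores$meth), modality = "meth",
               score = agg(scores$meth), stringsAsFactors = FALSE)
  )
  key <- if (aggregation == "mean_absolute") df$score else abs(df$score)
  df <- df[order(key, decreasing = TRUE), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Write an attribution ranking as TSV
#' @param ranking Data frame from [aggregate_and_rank()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_attribution_tsv <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stepwise feature-ablation study
#'
#' For each band of ranks (e.g. top 1-20), the named features are
#' zero-masked in both modalities and the model is retrained from
#' scratch with the same configuration and seed; held-out metrics are
#' recorded alongside a size-matched random band drawn from features
#' outside the requested bands.
#'
#' @param rna,meth Gene-level [omics_matrix] cohorts.
#' @param ranking Data frame from [aggregate_and_rank()].
#' @param bands List of integer rank ranges, e.g.
#'   `list(top_1_20 = 1:20)`.
#' @param arch,cfg Model and training configuration shared by all runs.
#' @param random_control Also run a size-matched random band per band?
#' @param control_seed Seed for drawing the random bands.
#' @return A data frame with one row per condition (baseline, each band,
#'   each random control) and held-out metric columns.
#' @export
ablate_features <- function(rna, meth, ranking, bands, arch = NULL,
                            cfg = train_config(), random_control = TRUE,
                            control_seed = 1L) {
  max_rank <- max(unlist(bands))
  if (max_rank > nrow(ranking)) stop("band exceeds the ranked feature count")
  ranking <- ranking[order(ranking$rank), , drop = FALSE]
  rows <- list()
  run <- function(mask, label) {
    fit <- fit_unpaired(rna, meth, arch = arch, cfg = cfg,
                        feature_mask = mask)
    m <- fit$metrics
    data.frame(condition = label, n_masked = length(mask),
               accuracy = m$accuracy, auc = m$auc, f1 = m$f1)
  }
  rows$baseline <- run(NULL, "baseline")
  banded_features <- unique(ranking$feature_id[unlist(bands)])
  for (bn in names(bands)) {
    feats <- unique(ranking$feature_id[bands[[bn]]])
    rows[[bn]] <- run(feats, bn)
    if (random_control) {
      pool <- setdiff(unique(ranking$feature_id), banded_features)
      ctrl <- with_seed(derive_seed(control_seed, bn),
                        sample(pool, length(feats)))
      rows[[paste0(bn, "_random")]] <- run(ctrl, paste0(bn, "_random"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Co-expression network among selected features
#'
#' Connects feature pairs whose Pearson correlation exceeds the
#' threshold in absolute value, across all (case and control) samples.
#' Constant features are excluded with a warning since their correlation
#' is undefined.
#'
#' @param x An [omics_matrix] (no missing entries).
#' @param features Feature IDs to include (default: all).
#' @param r_threshold Correlation threshold (default 0.75).
#' @return A list with `edges` (`feature_a`, `feature_b`, `r`),
#'   `degrees` (per-node degree) and `components` (connected-component
#'   membership).
#' @export
coexpression_network <- function(x, features = NULL, r_threshold = 0.75) {
  if (is.null(features)) features <- colnames(x$values)
  missing_feats <- setdiff(features, colnames(x$values))
  if (length(missing_feats))
    stop("features not present: ", paste(missing_feats, collapse = ", "))
  v <- x$values[, features, drop = FALSE]
  if (nrow(v) < 3L) stop("at least 3 samples are required")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant features: ",
            paste(features[sds == 0], collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
  }
  cm <- stats::cor(v)
  idx <- which(upper.tri(cm) & abs(cm) > r_threshold, arr.ind = TRUE)
  edges <- data.frame(feature_a = colnames(v)[idx[, 1L]],
                      feature_b = colnames(v)[idx[, 2L]],
                      r = cm[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = colnames(v))
  comps <- igraph::components(g)
  list(edges = edges,
       degrees = data.frame(feature_id = colnames(v),
                            degree = as.integer(igraph::degree(g)),
                            stringsAsFactors = FALSE),
       components = data.frame(feature_id = names(comps$membership),
                               component = as.integer(comps$membership),
                               stringsAsFactors = FALSE))
}
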