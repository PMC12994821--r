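# Optimization: Adam with L2 weight decay, plateau learning-rate
# scheduling, early stopping with best-validation checkpointing,
# stratified five-fold cross-validation on samples per modality, and
# single-modality fine-tuning of a pretrained model.

#' Training configuration
#'
#' @param learning_rate Initial Adam learning rate.
#' @param l2_strength Weight-decay coefficient (L2 regularization).
#' @param max_epochs Maximum training epochs.
#' @param scheduler_factor,scheduler_patience,min_lr Plateau scheduler:
#'   when the validation loss has not improved for `scheduler_patience`
#'   epochs the learning rate is multiplied by `scheduler_factor`, never
#'   dropping below `min_lr`.
#' @param early_stop_patience Epochs without validation improvement
#'   before training stops.
#' @param folds Cross-validation folds.
#' @param rna_per_batch Expression samples per mini-batch.
#' @param meth_per_rna Methylation samples paired with each expression
#'   sample in a mini-batch.
#' @param val_fraction Fraction of training samples (per class and
#'   modality) carved out as the inner validation set used for
#'   scheduling, early stopping and checkpoint selection.
#' @param seed Integer seed governing batching and masking.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, l2_strength = 1e-5,
                         max_epochs = 100L, scheduler_factor = 0.5,
                         scheduler_patience = 5L, min_lr = 1e-6,
                         early_stop_patience = 15L, folds = 5L,
                         rna_per_batch = 32L, meth_per_rna = 2L,
                         val_fraction = 0.25, seed = 1L) {
  cfg <- list(learning_rate = learning_rate, l2_strength = l2_strength,
              max_epochs = as.integer(max_epochs),
              scheduler_factor = scheduler_factor,
              scheduler_patience = as.integer(scheduler_patience),
              min_lr = min_lr,
              early_stop_patience = as.integer(early_stop_patience),
              folds = as.integer(folds),
              rna_per_batch = as.integer(rna_per_batch),
              meth_per_rna = as.integer(meth_per_rna),
              val_fraction = val_fraction,
              seed = as.integer(seed))
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$folds < 2L) stop("folds must be at least 2")
  class(cfg) <- "train_config"
  cfg
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(model, state, lr, weight_decay = 0,
                      trainable = NULL, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  nms <- if (is.null(trainable)) names(model$params) else trainable
  for (nm in nms) {
    p <- model$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$val
    m_ <- state$m[[nm]]
    v_ <- state$v[[nm]]
    if (is.null(m_)) { m_ <- g * 0; v_ <- g * 0 }
    m_ <- beta1 * m_ + (1 - beta1) * g
    v_ <- beta2 * v_ + (1 - beta2) * g * g
    state$m[[nm]] <- m_
    state$v[[nm]] <- v_
    p$val <- p$val - lr * (m_ / bc1) / (sqrt(v_ / bc2) + eps)
  }
  invisible(state)
}

# ---- plateau scheduler -----------------------------------------------------

#' Validation-plateau learning-rate scheduler
#'
#' Stateful helper: feed it the validation loss after each epoch with
#' `sched$update(loss)`; it returns the learning rate to use next. The
#' rate is multiplied by `factor` when the loss has not improved for
#' `patience` consecutive epochs, and never drops below `min_lr`.
#'
#' @param lr Initial learning rate.
#' @param factor Multiplicative reduction factor.
#' @param patience Epochs of no improvement tolerated before reduction.
#' @param min_lr Lower bound on the learning rate.
#' @return An environment with `update(loss)` and fields `lr`, `best`.
#' @export
plateau_scheduler <- function(lr, factor = 0.5, patience = 5L,
                              min_lr = 1e-6) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr
  e$best <- Inf
  e$wait <- 0L
  e$update <- function(loss) {
    if (loss < e$best - 1e-12) {
      e$best <- loss
      e$wait <- 0L
    } else {
      e$wait <- e$wait + 1L
      if (e$wait >= patience) {
        e$lr <- max(e$lr * factor, min_lr)
        e$wait <- 0L
      }
    }
    e$lr
  }
  e
}

# ---- core loop -------------------------------------------------------------

# Assemble mini-batch pair indices for one epoch: every training
# expression sample appears once per epoch; each is paired with
# `meth_per_rna` same-label methylation samples drawn fresh per batch.
epoch_batches <- function(rna_ids, rna_labels, meth_by_label, cfg) {
  ids <- sample(rna_ids)
  starts <- seq(1L, length(ids), by = cfg$rna_per_batch)
  lapply(starts, function(s) {
    chunk <- ids[s:min(s + cfg$rna_per_batch - 1L, length(ids))]
    meth_sel <- unlist(lapply(chunk, function(sid) {
      pool <- if (rna_labels[[sid]] == 1L) meth_by_label$case
              else meth_by_label$control
      pool[sample.int(length(pool), min(cfg$meth_per_rna, length(pool)))]
    }), use.names = FALSE)
    k <- min(cfg$meth_per_rna, min(lengths(meth_by_label)))
    new_pairing_plan(rep(chunk, each = k), meth_sel,
                     unlist(rna_labels[rep(chunk, each = k)], use.names = FALSE))
  })
}

# Evaluation forward over a pairing plan in chunks; returns per-pair
# scores, labels and the mean loss.
eval_pairs <- function(model, rna_vals, meth_vals, plan,
                       active = c("rna", "meth"), chunk = 512L) {
  n <- nrow(plan)
  scores <- numeric(n)
  loss_sum <- 0
  cls_sum <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    xr <- if (!is.null(rna_vals)) rna_vals[plan$rna_id[idx], , drop = FALSE]
    xm <- if (!is.null(meth_vals)) meth_vals[plan$meth_id[idx], , drop = FALSE]
    fw <- model_forward(model, xr, xm, training = FALSE)
    l <- model_loss_node(model, fw, plan$label[idx], active = active)
    scores[idx] <- as.numeric(tg_val(fw$prob))
    loss_sum <- loss_sum + l$breakdown[["total"]] * length(idx)
    cls_sum <- cls_sum + l$breakdown[["cls"]] * length(idx)
  }
  list(scores = scores, labels = plan$label, loss = loss_sum / n,
       cls_loss = cls_sum / n)
}

#' Train a model on intra-label pairs
#'
#' Runs Adam (with L2 weight decay) over label-consistent mini-batch
#' pairs, monitors a validation pairing for the plateau scheduler and
#' early stopping, and restores the best-validation parameters at the
#' end. The full per-epoch loss trajectory is recorded.
#'
#' @param model An initialized `omixfuse_model`.
#' @param rna_vals,meth_vals Numeric value matrices (rows named by sample
#'   ID, features scaled to the unit interval). Either may be `NULL` for
#'   single-modality training.
#' @param rna_labels,meth_labels Named 0/1 label vectors.
#' @param train_ids List with `rna` and `meth` training sample IDs.
#' @param val_plan A `pairing_plan` evaluated after each epoch.
#' @param cfg A [train_config()].
#' @param modality `"both"`, `"rna"` or `"meth"`; an ablated channel is
#'   fed a zero placeholder and its reconstruction losses are dropped.
#' @param trainable Optional character vector restricting which parameter
#'   groups are updated (used by fine-tuning).
#' @return The model (best-validation weights restored), with the epoch
#'   `trajectory` data frame and `best_epoch` attached.
#' @export
train_model <- function(model, rna_vals, meth_vals, rna_labels, meth_labels,
                        train_ids, val_plan, cfg,
                        modality = c("both", "rna", "meth"),
                        trainable = NULL) {
  modality <- match.arg(modality)
  active <- switch(modality, both = c("rna", "meth"), rna = "rna",
                   meth = "meth")
  single <- modality != "both"
  with_seed(cfg$seed, {
    opt <- adam_state()
    sched <- plateau_scheduler(cfg$learning_rate, cfg$scheduler_factor,
                               cfg$scheduler_patience, cfg$min_lr)
    best_auc <- -Inf
    best_val <- Inf
    best_snap <- snapshot_params(model)
    best_epoch <- 0L
    wait <- 0L
    lr <- cfg$learning_rate
    traj <- list()
    if (!single) {
      ml <- meth_labels[train_ids$meth]
      meth_by_label <- list(case = train_ids$meth[ml == 1L],
                            control = train_ids$meth[ml == 0L])
      if (min(lengths(meth_by_label)) == 0L)
        stop("training methylation samples must cover both classes")
    }
    anchor_ids <- if (modality == "meth") train_ids$meth else train_ids$rna
    anchor_labels <- if (modality == "meth") meth_labels else rna_labels
    if (length(anchor_ids) == 0L) stop("empty training set")
    for (epoch in seq_len(cfg$max_epochs)) {
      if (single) {
        ids <- sample(anchor_ids)
        starts <- seq(1L, length(ids), by = cfg$rna_per_batch)
        batches <- lapply(starts, function(s) {
          chunk <- ids[s:min(s + cfg$rna_per_batch - 1L, length(ids))]
          if (modality == "rna")
            new_pairing_plan(chunk, chunk, anchor_labels[chunk])
          else new_pairing_plan(chunk, chunk, anchor_labels[chunk])
        })
      } else {
        batches <- epoch_batches(train_ids$rna, rna_labels, meth_by_label, cfg)
      }
      acc <- NULL
      for (b in batches) {
        xr <- if (modality == "meth") NULL
              else rna_vals[b$rna_id, , drop = FALSE]
        xm <- if (modality == "rna") NULL
              else meth_vals[b$meth_id, , drop = FALSE]
        fw <- model_forward(model, xr, xm, training = TRUE)
        l <- model_loss_node(model, fw, b$label, active = active)
        if (!is.finite(l$breakdown[["total"]]))
          stop("non-finite training loss at epoch ", epoch,
               "; consider lowering the learning rate")
        tg_zero_grads(model$params)
        tg_backward(l$total)
        adam_step(model, opt, lr, cfg$l2_strength, trainable)
        acc <- if (is.null(acc)) l$breakdown else acc + l$breakdown
      }
      acc <- acc / length(batches)
      ev <- eval_pairs(model,
                       if (modality == "meth") NULL else rna_vals,
                       if (modality == "rna") NULL else meth_vals,
                       val_plan, active = active)
      lr <- sched$update(ev$loss)
      # Checkpoint selection tracks validation AUC (the headline metric);
      # the plateau scheduler monitors the validation loss.
      val_auc <- if (length(unique(ev$labels)) == 2L)
        roc_auc(ev$scores, ev$labels)$auc else -ev$loss
      traj[[epoch]] <- c(epoch = epoch, acc, val_loss = ev$loss,
                         val_auc = val_auc, lr = lr)
      improved <- val_auc > best_auc + 1e-9 ||
        (val_auc >= best_auc - 1e-9 && ev$cls_loss < best_val - 1e-12)
      if (improved) {
        best_auc <- max(best_auc, val_auc)
        best_val <- min(best_val, ev$cls_loss)
        best_snap <- snapshot_params(model)
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    restore_params(model, best_snap)
    model$trajectory <- as.data.frame(do.call(rbind, traj))
    model$best_epoch <- best_epoch
    model
  })
}

# ---- high-level fitting ----------------------------------------------------

# Scale both cohorts to the unit interval using training-sample
# statistics only.
scale_cohorts <- function(rna, meth, train_ids) {
  rs <- rescale_unit(om_subset(rna, samples = train_ids$rna))
  ms <- rescale_unit(om_subset(meth, samples = train_ids$meth))
  list(
    rna_vals = rescale_unit(rna, stats = rs$stats)$values,
    meth_vals = rescale_unit(meth, stats = ms$stats)$values,
    rna_stats = rs$stats, meth_stats = ms$stats
  )
}

#' Fit the fusion model on two unpaired cohorts with a held-out test split
#'
#' Convenience wrapper implementing the full protocol: stratified 80/20
#' sample-level split per modality, unit-interval scaling fitted on
#' training samples, an inner validation pairing carved from the training
#' samples for scheduling/early stopping, mini-batch pair training, and
#' per-pair test metrics.
#'
#' @param rna,meth Gene-level [omics_matrix] cohorts (aligned features,
#'   no missing entries).
#' @param arch Optional [arch_config()]; defaults to the reference
#'   desk-scale architecture for the given input dimension.
#' @param cfg A [train_config()].
#' @param test_fraction Held-out fraction per class and modality.
#' @param modality `"both"`, `"rna"` or `"meth"` (modality ablation).
#' @param feature_mask Optional character vector of feature IDs zeroed in
#'   both modalities before training (feature-ablation runs).
#' @return A list with the trained `model`, `metrics` (per-pair test
#'   [metrics_report()]), `per_sample` scores, `split`, scaling stats and
#'   the training trajectory.
#' @export
fit_unpaired <- function(rna, meth, arch = NULL, cfg = train_config(),
                         test_fraction = 0.2,
                         modality = c("both", "rna", "meth"),
                         feature_mask = NULL) {
  modality <- match.arg(modality)
  stopifnot(identical(colnames(rna$values), colnames(meth$values)))
  split_rna <- stratified_split(rna, test_fraction,
                                derive_seed(cfg$seed, "split_rna"))
  split_meth <- stratified_split(meth, test_fraction,
                                 derive_seed(cfg$seed, "split_meth"))
  train_ids <- list(rna = split_rna$train, meth = split_meth$train)
  test_ids <- list(rna = split_rna$test, meth = split_meth$test)
  sc <- scale_cohorts(rna, meth, train_ids)
  if (!is.null(feature_mask)) {
    sc$rna_vals[, feature_mask] <- 0
    sc$meth_vals[, feature_mask] <- 0
  }
  if (is.null(arch))
    arch <- arch_config(input_dim_rna = ncol(rna$values),
                        input_dim_meth = ncol(meth$values))
  model <- init_model(arch, seed = derive_seed(cfg$seed, "init"))
  rna_labels <- stats::setNames(rna$labels, rownames(rna$values))
  meth_labels <- stats::setNames(meth$labels, rownames(meth$values))

  # Inner validation split carved from the training samples.
  vf <- cfg$val_fraction
  inner_rna <- with_seed(derive_seed(cfg$seed, "inner_rna"), {
    ids <- train_ids$rna
    by_lab <- split(ids, rna_labels[ids])
    unlist(lapply(by_lab, function(g) sample(g, max(1L, round(vf * length(g))))),
           use.names = FALSE)
  })
  inner_meth <- with_seed(derive_seed(cfg$seed, "inner_meth"), {
    ids <- train_ids$meth
    by_lab <- split(ids, meth_labels[ids])
    unlist(lapply(by_lab, function(g) sample(g, max(1L, round(vf * length(g))))),
           use.names = FALSE)
  })
  core_ids <- list(rna = setdiff(train_ids$rna, inner_rna),
                   meth = setdiff(train_ids$meth, inner_meth))
  val_plan <- make_eval_plan(inner_rna, inner_meth, rna_labels, meth_labels,
                             modality)
  model <- train_model(model, sc$rna_vals, sc$meth_vals, rna_labels,
                       meth_labels, core_ids, val_plan, cfg,
                       modality = modality)
  test_plan <- make_eval_plan(test_ids$rna, test_ids$meth, rna_labels,
                              meth_labels, modality)
  ev <- eval_pairs(model, if (modality == "meth") NULL else sc$rna_vals,
                   if (modality == "rna") NULL else sc$meth_vals,
                   test_plan,
                   active = switch(modality, both = c("rna", "meth"),
                                   rna = "rna", meth = "meth"))
  anchor <- if (modality == "meth") "meth_id" else "rna_id"
  anchor_labels <- if (modality == "meth") meth_labels else rna_labels
  per_sample <- tapply(ev$scores, test_plan[[anchor]], mean)
  list(model = model,
       metrics = metrics_report(ev$scores, ev$labels),
       metrics_sample = metrics_report(
         as.numeric(per_sample),
         as.integer(anchor_labels[names(per_sample)])),
       per_sample = per_sample,
       split = list(rna = split_rna, meth = split_meth),
       scaling = sc[c("rna_stats", "meth_stats")],
       scaled = list(rna = sc$rna_vals, meth = sc$meth_vals),
       test_plan = test_plan,
       trajectory = model$trajectory,
       modality = modality)
}

# Pair-level evaluation plan; single-modality runs anchor each sample to
# itself so every sample is scored exactly once.
make_eval_plan <- function(rna_ids, meth_ids, rna_labels, meth_labels,
                           modality = "both") {
  if (modality == "rna")
    return(new_pairing_plan(rna_ids, rna_ids, rna_labels[rna_ids], "test"))
  if (modality == "meth")
    return(new_pairing_plan(meth_ids, meth_ids, meth_labels[meth_ids], "test"))
  plans <- lapply(c(1L, 0L), function(lab) {
    enumerate_pairs(rna_ids[rna_labels[rna_ids] == lab],
                    meth_ids[meth_labels[meth_ids] == lab], lab,
                    role = "test")
  })
  out <- do.call(rbind, plans)
  class(out) <- c("pairing_plan", "data.frame")
  out
}

#' Stratified k-fold cross-validation of the fusion model
#'
#' Folds are drawn on samples per modality (stratified by label); pairs
#' are enumerated within each fold's training and validation sample sets,
#' so no sample contributes pairs to both sides of any fold.
#'
#' @param rna,meth Gene-level [omics_matrix] cohorts.
#' @param arch Optional [arch_config()].
#' @param cfg A [train_config()]; `cfg$folds` controls the fold count.
#' @param modality Modality condition, as in [fit_unpaired()].
#' @return A list with per-fold results (per-pair `metrics`, sample-level
#'   `metrics_sample`, sample IDs, trajectory) and a `summary` data frame
#'   of mean and sd per metric (including `auc_sample` and
#'   `accuracy_sample`).
#' @export
cross_validate <- function(rna, meth, arch = NULL, cfg = train_config(),
                           modality = c("both", "rna", "meth")) {
  modality <- match.arg(modality)
  folds_rna <- stratified_folds(rna, cfg$folds, derive_seed(cfg$seed, "cv_rna"))
  folds_meth <- stratified_folds(meth, cfg$folds,
                                 derive_seed(cfg$seed, "cv_meth"))
  rna_labels <- stats::setNames(rna$labels, rownames(rna$values))
  meth_labels <- stats::setNames(meth$labels, rownames(meth$values))
  if (is.null(arch))
    arch <- arch_config(input_dim_rna = ncol(rna$values),
                        input_dim_meth = ncol(meth$values))
  fold_results <- lapply(seq_len(cfg$folds), function(i) {
    val_ids <- list(rna = folds_rna[[i]], meth = folds_meth[[i]])
    train_ids <- list(rna = setdiff(rownames(rna$values), val_ids$rna),
                      meth = setdiff(rownames(meth$values), val_ids$meth))
    sc <- scale_cohorts(rna, meth, train_ids)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, paste0("fold", i))
    model <- init_model(arch, seed = derive_seed(fold_cfg$seed, "init"))
    val_plan <- make_eval_plan(val_ids$rna, val_ids$meth, rna_labels,
                               meth_labels, modality)
    model <- train_model(model, sc$rna_vals, sc$meth_vals, rna_labels,
                         meth_labels, train_ids, val_plan, fold_cfg,
                         modality = modality)
    ev <- eval_pairs(model, if (modality == "meth") NULL else sc$rna_vals,
                     if (modality == "rna") NULL else sc$meth_vals, val_plan,
                     active = switch(modality, both = c("rna", "meth"),
                                     rna = "rna", meth = "meth"))
    anchor <- if (modality == "meth") "meth_id" else "rna_id"
    anchor_labels <- if (modality == "meth") meth_labels else rna_labels
    per_sample <- tapply(ev$scores, val_plan[[anchor]], mean)
    list(fold = i, metrics = metrics_report(ev$scores, ev$labels),
         metrics_sample = metrics_report(
           as.numeric(per_sample),
           as.integer(anchor_labels[names(per_sample)])),
         val_ids = val_ids, trajectory = model$trajectory, model = model)
  })
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  tab <- t(vapply(fold_results, function(fr)
    c(unlist(fr$metrics[metric_names]),
      accuracy_sample = fr$metrics_sample$accuracy,
      auc_sample = fr$metrics_sample$auc), numeric(7)))
  summary_df <- data.frame(metric = colnames(tab),
                           mean = colMeans(tab),
                           sd = apply(tab, 2L, stats::sd),
                           row.names = NULL)
  list(folds = fold_results, summary = summary_df, per_fold = tab)
}

#' Fine-tune a pretrained model on a single expression cohort
#'
#' Freezes the autoencoders and the methylation channel; only the
#' expression Transformer encoder, the classifier head and (by default)
#' the fusion layer are updated. The methylation channel is fed a zero
#' placeholder. Per-sample fused latent representations are exported for
#' downstream use.
#'
#' @param model A pretrained `omixfuse_model`.
#' @param rna An expression [omics_matrix] aligned to the model's input
#'   features.
#' @param cfg A [train_config()].
#' @param update_fusion Also update the fusion projection?
#' @param test_fraction Held-out fraction for validation metrics.
#' @return A list with the adapted `model`, `latents` (samples x
#'   fusion_dim), `metrics` on the held-out samples and the trajectory.
#' @export
fine_tune_single_modality <- function(model, rna, cfg = train_config(),
                                      update_fusion = TRUE,
                                      test_fraction = 0.2) {
  if (rna$modality != "expression")
    stop("fine_tune_single_modality expects an expression cohort")
  if (ncol(rna$values) != model$arch$input_dim_rna)
    stop("cohort features do not match the pretrained input dimension")
  trainable <- grep("^(rna\\.enc|cls\\.)", names(model$params), value = TRUE)
  if (update_fusion)
    trainable <- c(trainable, grep("^fusion\\.", names(model$params),
                                   value = TRUE))
  split <- stratified_split(rna, test_fraction, derive_seed(cfg$seed, "ft"))
  sc <- rescale_unit(om_subset(rna, samples = split$train))
  vals <- rescale_unit(rna, stats = sc$stats)$values
  labels <- stats::setNames(rna$labels, rownames(rna$values))
  val_plan <- make_eval_plan(split$test, NULL, labels, NULL, "rna")
  model <- train_model(model, vals, NULL, labels, NULL,
                       list(rna = split$train, meth = character(0)),
                       val_plan, cfg, modality = "rna", trainable = trainable)
  ev <- eval_pairs(model, vals, NULL, val_plan, active = "rna")
  all_plan <- make_eval_plan(rownames(vals), NULL, labels, NULL, "rna")
  fw <- predict_pairs(model, vals, NULL)
  latents <- fw$fused
  rownames(latents) <- rownames(vals)
  list(model = model, latents = latents,
       metrics = metrics_report(ev$scores, ev$labels),
       split = split, trajectory = model$trajectory)
}

#' Export per-sample latent representations as TSV
#' @param latents Matrix with sample IDs as row names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_latents <- function(latents, path) {
  df <- data.frame(sample_id = rownames(latents), latents,
                   check.names = FALSE)
  colnames(df) <- c("sample_id", sprintf("dim%02d", seq_len(ncol(latents))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
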