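# End-to-end pipeline orchestration: simulate (or load) -> preprocess ->
# split/pair -> train -> evaluate -> attribute -> report. Every stage
# derives its seed deterministically from the global seed and the stage
# name, so one seed reproduces the whole run.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    synthetic = TRUE,
    test_fraction = 0.2,
    data = list(rna_path = NULL, meth_path = NULL),
    synth = list(),
    preprocess = list(max_missing = 0.30),
    arch = list(),
    train = list(),
    attribution = list(baseline = "zeros", n_steps = 64L, n_samples = 10L)
  )
}

#' Validate a pipeline configuration
#'
#' Parses YAML (a file path or raw text), fills defaults, and collects
#' every problem before reporting: errors are raised together, unknown
#' keys produce warnings (forward compatibility), and a valid
#' configuration is returned with all defaults echoed.
#'
#' @param raw A YAML file path, YAML text, or a named list.
#' @return The validated `pipeline_config` list.
#' @export
validate_config <- function(raw = NULL) {
  cfg <- pipeline_defaults()
  user <- NULL
  if (is.list(raw)) {
    user <- raw
  } else if (!is.null(raw) && nzchar(raw)) {
    user <- if (file.exists(raw)) yaml::read_yaml(raw)
            else yaml::yaml.load(raw)
  }
  errors <- character(0)
  if (!is.null(user)) {
    known <- names(cfg)
    unknown <- setdiff(names(user), known)
    if (length(unknown))
      warning("ignoring unknown configuration keys: ",
              paste(unknown, collapse = ", "))
    for (nm in intersect(names(user), known)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  if (!is.null(cfg$train$learning_rate) && cfg$train$learning_rate <= 0)
    errors <- c(errors, "train.learning_rate must be positive")
  if (!is.null(cfg$synth$missing_rate) &&
      (cfg$synth$missing_rate < 0 || cfg$synth$missing_rate >= 1))
    errors <- c(errors, "synth.missing_rate must be in [0, 1)")
  if (!isTRUE(cfg$synthetic)) {
    for (p in c("rna_path", "meth_path")) {
      if (is.null(cfg$data[[p]]))
        errors <- c(errors, paste0("data.", p,
                                   " is required when synthetic mode is off"))
      else if (!file.exists(cfg$data[[p]]))
        errors <- c(errors, paste0("data.", p, ": file not found: ",
                                   cfg$data[[p]]))
    }
  }
  if (!is.null(cfg$attribution$n_steps) && cfg$attribution$n_steps < 1)
    errors <- c(errors, "attribution.n_steps must be at least 1")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> preprocess -> split/pair -> train ->
#' evaluate -> attribute -> report, writing each stage's artifacts under
#' `out_dir` and a manifest listing them together with the configuration
#' echo, package version and the loss trajectory of the training stage.
#' Re-running with the same configuration and seed reproduces all
#' metrics.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param out_dir Run directory (created if needed).
#' @return The manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arts <- new.env(parent = emptyenv())
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- function(...) file.path(out_dir, ...)

  # --- simulate / load ---
  cohort <- stage("simulate", {
    if (isTRUE(cfg$synthetic)) {
      sc_args <- cfg$synth
      sc_args$seed <- derive_seed(cfg$seed, "simulate")
      cohort <- generate_unpaired_cohort(do.call(synth_config, sc_args))
    } else {
      cohort <- list(
        rna = read_omics_delim(cfg$data$rna_path, "expression"),
        meth = read_omics_delim(cfg$data$meth_path, "methylation"),
        truth = NULL
      )
    }
    dir.create(paths("data"), showWarnings = FALSE)
    write_omics_tsv(cohort$rna, paths("data", "rna.tsv"))
    write_omics_tsv(cohort$meth, paths("data", "meth.tsv"))
    if (!is.null(cohort$truth))
      write_ground_truth(cohort$truth, paths("data", "truth.json"))
    arts$simulate <- paths("data", "rna.tsv")
    cohort
  })

  # --- preprocess ---
  pp <- stage("preprocess", {
    rna <- filter_missing(cohort$rna, cfg$preprocess$max_missing)
    meth <- filter_missing(cohort$meth, cfg$preprocess$max_missing)
    both <- intersect_features(rna, meth)
    write_omics_tsv(both$rna, paths("data", "rna_processed.tsv"))
    write_omics_tsv(both$meth, paths("data", "meth_processed.tsv"))
    arts$preprocess <- paths("data", "rna_processed.tsv")
    both
  })

  # --- split / pair / train / evaluate (shared fit) ---
  tr_args <- cfg$train
  tr_args$seed <- derive_seed(cfg$seed, "train")
  tr_cfg <- do.call(train_config, tr_args)
  arch <- if (length(cfg$arch)) {
    a <- cfg$arch
    a$input_dim_rna <- ncol(pp$rna$values)
    a$input_dim_meth <- ncol(pp$meth$values)
    do.call(arch_config, a)
  } else NULL
  fit <- stage("train", {
    fit_unpaired(pp$rna, pp$meth, arch = arch, cfg = tr_cfg,
                 test_fraction = cfg$test_fraction)
  })
  stage("split", {
    dir.create(paths("splits"), showWarnings = FALSE)
    jsonlite::write_json(
      list(rna = fit$split$rna[c("train", "test")],
           meth = fit$split$meth[c("train", "test")]),
      paths("splits", "split.json"), auto_unbox = FALSE)
    write_pairing_plan(fit$test_plan, paths("splits", "test_pairs.tsv"))
    arts$split <- paths("splits", "split.json")
  })
  stage("train-artifacts", {
    dir.create(paths("model"), showWarnings = FALSE)
    save_checkpoint(fit$model, paths("model", "checkpoint.json"))
    # JSON-lines log: one record per epoch with every loss term
    traj <- fit$trajectory
    writeLines(
      vapply(seq_len(nrow(traj)), function(i) {
        jsonlite::toJSON(as.list(traj[i, ]), auto_unbox = TRUE, digits = NA)
      }, ""),
      paths("model", "training_log.jsonl"))
    arts$train <- paths("model", "checkpoint.json")
  })
  stage("evaluate", {
    dir.create(paths("metrics"), showWarnings = FALSE)
    write_metrics_json(fit$metrics, paths("metrics", "metrics.json"))
    arts$evaluate <- paths("metrics", "metrics.json")
  })

  # --- attribute ---
  ranking <- stage("attribute", {
    n_attr <- min(cfg$attribution$n_samples, nrow(fit$test_plan))
    idx <- with_seed(derive_seed(cfg$seed, "attribute"),
                     sample(nrow(fit$test_plan), n_attr))
    scores <- attribute_pairs(fit$model, fit$scaled$rna, fit$scaled$meth,
                              fit$test_plan[idx, , drop = FALSE],
                              baseline = cfg$attribution$baseline,
                              n_steps = cfg$attribution$n_steps)
    ranking <- aggregate_and_rank(scores)
    dir.create(paths("attribution"), showWarnings = FALSE)
    write_attribution_tsv(ranking, paths("attribution", "ranking.tsv"))
    arts$attribute <- paths("attribution", "ranking.tsv")
    ranking
  })

  # --- report ---
  manifest <- stage("report", {
    traj <- fit$trajectory
    cyc_cols <- intersect(c("cyc_rna", "cyc_meth"), colnames(traj))
    best <- fit$model$best_epoch
    manifest <- list(
      package_version = as.character(utils::packageVersion("omixfuse")),
      seed = cfg$seed,
      config = unclass(cfg),
      artifacts = mget(c("simulate", "preprocess", "split", "train",
                         "evaluate", "attribute"), envir = arts),
      loss = list(
        first_epoch = as.list(traj[1L, c("cls", cyc_cols, "total")]),
        final_epoch = as.list(traj[nrow(traj), c("cls", cyc_cols, "total")]),
        best_epoch_index = best,
        best_epoch = as.list(traj[best, c("cls", cyc_cols, "total")])
      ),
      metrics = list(accuracy = fit$metrics$accuracy, auc = fit$metrics$auc,
                     f1 = fit$metrics$f1)
    )
    manifest$artifacts$report <- paths("manifest.json")
    jsonlite::write_json(manifest, paths("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    manifest
  })
  invisible(manifest)
}
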