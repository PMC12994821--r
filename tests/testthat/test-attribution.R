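# Attribution against closed forms and independent numerical oracles.

linear_fgrad <- function(w) {
  function(m) list(f = as.numeric(m %*% w),
                   grad = matrix(w, nrow(m), length(w), byrow = TRUE))
}

test_that("attribution of a linear function is exact for any step count", {
  set.seed(1)
  w <- rnorm(7)
  x <- rnorm(7)
  for (n in c(1L, 10L, 100L)) {
    for (rule in c("right", "trapezoid")) {
      out <- integrated_gradients_fn(linear_fgrad(w), x, rep(0, 7),
                                     n_steps = n, rule = rule)
      expect_equal(out$scores, w * x, tolerance = 1e-6 * max(abs(w * x)))
      expect_lt(out$completeness_gap, 1e-10)
    }
  }
  # nonzero baseline: scores are w_i * (x_i - b_i)
  b <- rnorm(7)
  out <- integrated_gradients_fn(linear_fgrad(w), x, b, n_steps = 5L)
  expect_equal(out$scores, w * (x - b), tolerance = 1e-9)
})

test_that("quadratic attribution converges to the exact path integral", {
  fq <- function(m) list(f = rowSums(m^2), grad = 2 * m)
  # right-endpoint sum at n = 1 evaluates the gradient at x only
  out1 <- integrated_gradients_fn(fq, 1, 0, n_steps = 1L, rule = "right")
  expect_equal(out1$scores, 2)
  # independent oracle: fine-Riemann reference at n = 1e5
  fine <- integrated_gradients_fn(fq, 1, 0, n_steps = 1e5L, rule = "right")
  expect_equal(fine$scores, 1, tolerance = 1e-4)
  # trapezoid is exact for a quadratic integrand at any n
  out_t <- integrated_gradients_fn(fq, 1, 0, n_steps = 1L,
                                   rule = "trapezoid")
  expect_equal(out_t$scores, 1, tolerance = 1e-12)
  expect_error(integrated_gradients_fn(fq, 1, 0, n_steps = 0L), "n_steps")
})

test_that("attribution at the baseline is identically zero", {
  model <- tiny_model(p_rna = 10L, p_meth = 10L)
  ig <- integrated_gradients(model, rep(0, 10), rep(0, 10), n_steps = 4L)
  expect_equal(ig$rna, rep(0, 10))
  expect_equal(ig$meth, rep(0, 10))
  # all-ones baseline with x = ones likewise
  ig2 <- integrated_gradients(model, rep(1, 10), rep(1, 10),
                              baseline = "ones", n_steps = 4L)
  expect_equal(max(abs(c(ig2$rna, ig2$meth))), 0)
})

test_that("model attribution satisfies completeness as steps grow", {
  model <- tiny_model(p_rna = 12L, p_meth = 12L, seed = 4)
  set.seed(2)
  xr <- runif(12)
  xm <- runif(12)
  ig <- integrated_gradients(model, xr, xm, n_steps = 512L)
  expect_lt(ig$completeness_gap_rel, 0.05)
  coarse <- integrated_gradients(model, xr, xm, n_steps = 8L)
  # both approximate the same integral
  expect_equal(sum(ig$rna) + sum(ig$meth),
               sum(coarse$rna) + sum(coarse$meth), tolerance = 0.05)
})

test_that("aggregation rules and ranking behave as defined", {
  scores <- list(
    rna = matrix(c(1, -1, 0.2, 0.2), 2L, 2L,
                 dimnames = list(NULL, c("gA", "gB"))),
    meth = matrix(c(0.1, 0.1, 3, -3), 2L, 2L,
                  dimnames = list(NULL, c("gA", "gB")))
  )
  # mean-absolute: +a and -a average to a; signed mean cancels to 0
  ma <- aggregate_and_rank(scores, "mean_absolute")
  expect_equal(ma$score[ma$feature_id == "gA" & ma$modality == "rna"], 1)
  sm <- aggregate_and_rank(scores, "signed_mean")
  expect_equal(sm$score[sm$feature_id == "gA" & sm$modality == "rna"], 0)
  # the uniformly dominant feature ranks first
  expect_equal(ma$feature_id[ma$rank == 1L], "gB")
  expect_equal(ma$modality[ma$rank == 1L], "meth")
  expect_setequal(ma$rank, 1:4)
  # single sample: aggregate equals that sample's absolute scores
  one <- lapply(scores, function(m) m[1L, , drop = FALSE])
  expect_equal(aggregate_and_rank(one)$score,
               sort(abs(c(one$rna[1, ], one$meth[1, ])), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_error(aggregate_and_rank(list(rna = scores$rna[0, , drop = FALSE],
                                       meth = scores$meth[0, , drop = FALSE])),
               "no attributed samples")
})

test_that("co-expression networks recover planted correlation structure", {
  set.seed(5)
  n <- 200L
  shared <- rnorm(n)
  vals <- cbind(
    f1 = 0.95 * shared + sqrt(1 - 0.95^2) * rnorm(n),
    f2 = 0.95 * shared + sqrt(1 - 0.95^2) * rnorm(n),
    f3 = 0.95 * shared + sqrt(1 - 0.95^2) * rnorm(n),
    matrix(rnorm(n * 6), n, 6L,
           dimnames = list(NULL, sprintf("noise%d", 1:6)))
  )
  x <- omics_matrix(vals, sprintf("s%03d", 1:n), colnames(vals),
                    rep_len(0:1, n), "expression")
  net <- coexpression_network(x, r_threshold = 0.75)
  in_module <- net$edges$feature_a %in% c("f1", "f2", "f3") &
    net$edges$feature_b %in% c("f1", "f2", "f3")
  expect_equal(nrow(net$edges[in_module, ]), 3L)
  # independent noise features yield no edges at this threshold and n
  expect_equal(nrow(net$edges[!in_module, ]), 0L)
  comp <- net$components
  expect_length(unique(comp$component[comp$feature_id %in%
                                        c("f1", "f2", "f3")]), 1L)
  # an exactly duplicated feature gives r = 1
  dup <- omics_matrix(cbind(a = vals[, 1L], b = vals[, 1L]),
                      sprintf("s%03d", 1:n), c("a", "b"),
                      rep_len(0:1, n), "expression")
  dnet <- coexpression_network(dup)
  expect_equal(dnet$edges$r, 1)
  expect_equal(dnet$degrees$degree, c(1L, 1L))
})

test_that("co-expression excludes constant features with a warning", {
  vals <- cbind(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  x <- omics_matrix(vals, sprintf("s%d", 1:10), colnames(vals),
                    rep_len(0:1, 10), "expression")
  expect_warning(net <- coexpression_network(x), "constant")
  expect_false("b" %in% net$degrees$feature_id)
  expect_error(coexpression_network(x, features = "zz"), "not present")
  tiny <- omics_matrix(vals[1:2, ], c("s1", "s2"), colnames(vals),
                       c(0, 1), "expression")
  expect_error(suppressWarnings(coexpression_network(tiny)), "3 samples")
})

test_that("attribution rankings serialize to TSV", {
  ranking <- data.frame(feature_id = c("gA", "gB"),
                        modality = c("rna", "meth"),
                        score = c(0.5, 0.2), rank = 1:2)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_attribution_tsv(ranking, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back, ranking)
})

test_that("ensemble score averaging normalizes each model to unit mean", {
  a <- c(f1 = 10, f2 = 0, f3 = 0)   # strong model, concentrated
  b <- c(f1 = 0, f2 = 0.1, f3 = 0)  # weak model, different feature
  avg <- omixfuse:::ensemble_scores(list(a, b))
  # both models contribute equally after normalization
  expect_equal(unname(avg["f1"]), unname(avg["f2"]))
  expect_equal(unname(avg["f3"]), 0)
  single <- omixfuse:::ensemble_scores(list(a))
  expect_equal(single, a / mean(a))
})

test_that("fold-averaged attribution produces a full joint ranking", {
  cohort <- tiny_cohort(seed = 12)
  pp <- intersect_features(cohort$rna, cohort$meth)
  cv <- cross_validate(pp$rna, pp$meth,
                       arch = tiny_arch(ncol(pp$rna$values),
                                        ncol(pp$meth$values)),
                       cfg = train_config(max_epochs = 2L, folds = 3L,
                                          rna_per_batch = 16L, seed = 1))
  rk <- attribute_cv(cv, pp$rna, pp$meth, n_pairs = 4L, n_steps = 8L,
                     seed = 1)
  expect_equal(nrow(rk), 2L * ncol(pp$rna$values))
  expect_setequal(rk$rank, seq_len(nrow(rk)))
  expect_setequal(unique(rk$modality), c("rna", "meth"))
  expect_true(all(diff(rk$score) <= 1e-12))
})

test_that("feature-ablation retraining records bands and matched controls", {
  cohort <- tiny_cohort(seed = 13)
  pp <- intersect_features(cohort$rna, cohort$meth)
  ranking <- data.frame(
    feature_id = c(cohort$truth$informative_rna,
                   setdiff(colnames(pp$rna$values),
                           cohort$truth$informative_rna)),
    modality = "rna", stringsAsFactors = FALSE)
  ranking$rank <- seq_len(nrow(ranking))
  cfg <- train_config(max_epochs = 2L, early_stop_patience = 2L,
                      rna_per_batch = 16L, seed = 4)
  arch <- tiny_arch(ncol(pp$rna$values), ncol(pp$meth$values))
  tab <- ablate_features(pp$rna, pp$meth, ranking,
                         bands = list(top_1_5 = 1:5),
                         arch = arch, cfg = cfg, control_seed = 9)
  expect_equal(tab$condition, c("baseline", "top_1_5", "top_1_5_random"))
  expect_equal(tab$n_masked, c(0L, 5L, 5L))
  # the baseline row reproduces an identical direct fit (same seed)
  direct <- fit_unpaired(pp$rna, pp$meth, arch = arch, cfg = cfg)
  expect_equal(tab$auc[1L], direct$metrics$auc)
  expect_error(ablate_features(pp$rna, pp$meth, ranking,
                               bands = list(b = 1:10000)), "exceeds")
})
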