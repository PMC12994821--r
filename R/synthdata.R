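# Synthetic unpaired two-modality cohorts with known ground truth.
#
# Generative model: every sample draws shared latent factors. Factor 1 is
# the disease factor: cases receive a +effect_size shift on it and it
# carries a within-class dispersion of 0.4 sd (shared biological
# heterogeneity); informative features load on it exclusively and with
# unit weight, so the class-conditional mean of an informative feature
# differs by effect_size in expectation (on the linear-predictor scale
# for methylation) and the feature-level effect size is the binding
# determinant of separability. The remaining factors are standard normal
# background shared by the non-informative features only.
# Expression = linear map of the factors + Gaussian noise; methylation =
# logistic squash of a linear map (plus a per-feature baseline offset) so
# every value is a beta value in [0, 1]. The two cohorts are drawn as
# independent sample sets with disjoint IDs: unpairedness is structural,
# never simulated by shuffling a paired draw.

#' Configuration for the synthetic cohort generator
#'
#' @param n_rna_samples,n_meth_samples Cohort sizes (the two cohorts are
#'   independent and share no samples).
#' @param n_genes Number of gene-level features per modality.
#' @param n_informative_rna,n_informative_meth Number of features per
#'   modality carrying class signal.
#' @param effect_size Shift of the disease factor between classes; equals
#'   the expected class-conditional mean difference of an informative
#'   feature before noise (logit scale for methylation).
#' @param latent_dim Number of shared generative factors (>= 2; factor 1
#'   is the disease factor).
#' @param noise_sd Per-feature Gaussian noise standard deviation.
#' @param missing_rate Fraction of entries set to missing, in \[0, 1).
#' @param case_fraction Fraction of case samples, in (0, 1).
#' @param seed Integer seed; generation is a pure function of it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_rna_samples = 200L, n_meth_samples = 120L,
                         n_genes = 400L, n_informative_rna = 20L,
                         n_informative_meth = 20L, effect_size = 1.5,
                         latent_dim = 8L, noise_sd = 1, missing_rate = 0.05,
                         case_fraction = 0.5, seed = 1L) {
  cfg <- list(
    n_rna_samples = as.integer(n_rna_samples),
    n_meth_samples = as.integer(n_meth_samples),
    n_genes = as.integer(n_genes),
    n_informative_rna = as.integer(n_informative_rna),
    n_informative_meth = as.integer(n_informative_meth),
    effect_size = effect_size, latent_dim = as.integer(latent_dim),
    noise_sd = noise_sd, missing_rate = missing_rate,
    case_fraction = case_fraction, seed = as.integer(seed)
  )
  for (f in c("n_rna_samples", "n_meth_samples", "n_genes", "latent_dim")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("invalid synth_config: '", f, "' must be a positive count")
  }
  for (f in c("n_informative_rna", "n_informative_meth")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L || cfg[[f]] > cfg$n_genes)
      stop("invalid synth_config: '", f, "' must be in [0, n_genes]")
  }
  if (cfg$latent_dim < 2L)
    stop("invalid synth_config: 'latent_dim' must be at least 2")
  if (cfg$effect_size < 0)
    stop("invalid synth_config: 'effect_size' must be non-negative")
  if (cfg$noise_sd < 0)
    stop("invalid synth_config: 'noise_sd' must be non-negative")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid synth_config: 'missing_rate' must be in [0, 1)")
  if (cfg$case_fraction <= 0 || cfg$case_fraction >= 1)
    stop("invalid synth_config: 'case_fraction' must be in (0, 1)")
  class(cfg) <- "synth_config"
  cfg
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed for a named pipeline stage, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

make_labels <- function(n, case_fraction) {
  n_case <- round(n * case_fraction)
  n_case <- min(max(n_case, 1L), n - 1L)
  sample(c(rep(1L, n_case), rep(0L, n - n_case)))
}

#' Generate two unpaired synthetic cohorts with ground truth
#'
#' @param config A [synth_config()].
#' @return A list with elements `rna` and `meth` ([omics_matrix] objects)
#'   and `truth` (informative feature IDs per modality, per-sample latent
#'   factors, and labels per modality).
#' @export
generate_unpaired_cohort <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  with_seed(config$seed, {
    lab_rna <- make_labels(config$n_rna_samples, config$case_fraction)
    lab_meth <- make_labels(config$n_meth_samples, config$case_fraction)

    inf_rna <- sort(sample(config$n_genes, config$n_informative_rna))
    inf_meth <- sort(sample(config$n_genes, config$n_informative_meth))

    # Loadings: the disease factor (column 1 of z) feeds informative
    # features exclusively and with unit weight; background factors feed
    # the remaining features weakly.
    make_loadings <- function(informative) {
      l <- rbind(0, matrix(stats::rnorm((config$latent_dim - 1L) * config$n_genes,
                                        sd = 0.4),
                           config$latent_dim - 1L, config$n_genes))
      l[, informative] <- 0
      l[1L, informative] <- 1
      l
    }
    l_rna <- make_loadings(inf_rna)
    l_meth <- make_loadings(inf_meth)
    meth_baseline <- stats::rnorm(config$n_genes, sd = 1.2)

    draw_modality <- function(n, labels, loadings, link) {
      z <- matrix(stats::rnorm(n * config$latent_dim), n, config$latent_dim)
      z[, 1L] <- 0.4 * z[, 1L] + config$effect_size * labels
      lin <- z %*% loadings +
        matrix(stats::rnorm(n * config$n_genes, sd = config$noise_sd),
               n, config$n_genes)
      list(z = z, x = link(lin))
    }
    rna_draw <- draw_modality(config$n_rna_samples, lab_rna, l_rna, identity)
    meth_draw <- draw_modality(
      config$n_meth_samples, lab_meth, l_meth,
      function(lin) stats::plogis(sweep(lin, 2L, -meth_baseline))
    )

    rna <- omics_matrix(rna_draw$x,
                        sprintf("rna_s%04d", seq_len(config$n_rna_samples)),
                        gene_ids, lab_rna, "expression")
    meth <- omics_matrix(meth_draw$x,
                         sprintf("meth_s%04d", seq_len(config$n_meth_samples)),
                         gene_ids, lab_meth, "methylation")
    if (config$missing_rate > 0) {
      rna <- inject_missingness(rna, config$missing_rate,
                                derive_seed(config$seed, "missing_rna"))
      meth <- inject_missingness(meth, config$missing_rate,
                                 derive_seed(config$seed, "missing_meth"))
    }
    truth <- list(
      informative_rna = gene_ids[inf_rna],
      informative_meth = gene_ids[inf_meth],
      latent_rna = rna_draw$z, latent_meth = meth_draw$z,
      labels_rna = lab_rna, labels_meth = lab_meth
    )
    list(rna = rna, meth = meth, truth = truth)
  })
}

#' Set entries of a matrix to missing at random
#'
#' Each entry is independently set to missing with probability `rate`;
#' already-missing entries stay missing. IDs, labels and modality are
#' unchanged, and the mask is a pure function of `seed`.
#'
#' @param x An [omics_matrix].
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed for the mask.
#' @return The matrix with missing entries injected.
#' @export
inject_missingness <- function(x, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(x)
  v <- x$values
  mask <- with_seed(seed, stats::runif(length(v)) < rate)
  v[mask] <- NA_real_
  omics_matrix(v, rownames(x$values), colnames(x$values), x$labels, x$modality)
}

#' Tiny fixed two-cohort fixture used in documentation and exact tests
#'
#' Six expression samples and four methylation samples over eight genes;
#' genes gA, gB and gC carry class signal. The values are hard-coded so
#' every call returns identical content.
#'
#' @return A list with `rna`, `meth` and `truth` as in
#'   [generate_unpaired_cohort()].
#' @export
make_worked_example <- function() {
  genes <- c("gA", "gB", "gC", "gD", "gE", "gF", "gG", "gH")
  rna_vals <- matrix(c(
    #  gA     gB     gC     gD     gE     gF     gG     gH
    2.10,  1.80,  2.40, -0.30,  0.50, -0.10,  0.90, -0.70,  # case
    1.70,  2.20,  1.90,  0.40, -0.60,  0.80, -0.20,  0.10,  # case
    2.50,  1.60,  2.10, -0.50,  0.20,  0.30, -0.90,  0.60,  # case
    0.20, -0.40,  0.10,  0.60, -0.30, -0.80,  0.40, -0.20,  # control
    -0.30,  0.50, -0.20, -0.10,  0.70,  0.20, -0.50,  0.90,  # control
    0.10, -0.20,  0.30,  0.80, -0.40,  0.60,  0.20, -0.60   # control
  ), nrow = 6L, byrow = TRUE)
  meth_vals <- matrix(c(
    0.82, 0.78, 0.85, 0.40, 0.55, 0.35, 0.60, 0.45,  # case
    0.76, 0.81, 0.79, 0.52, 0.38, 0.62, 0.41, 0.58,  # case
    0.31, 0.28, 0.35, 0.48, 0.61, 0.44, 0.57, 0.39,  # control
    0.26, 0.33, 0.29, 0.55, 0.42, 0.58, 0.36, 0.63   # control
  ), nrow = 4L, byrow = TRUE)
  rna <- omics_matrix(rna_vals, sprintf("rna_w%d", 1:6), genes,
                      c(1, 1, 1, 0, 0, 0), "expression")
  meth <- omics_matrix(meth_vals, sprintf("meth_w%d", 1:4), genes,
                       c(1, 1, 0, 0), "methylation")
  list(
    rna = rna, meth = meth,
    truth = list(informative_rna = genes[1:3], informative_meth = genes[1:3],
                 labels_rna = rna$labels, labels_meth = meth$labels)
  )
}

#' Write the generator's ground truth as a JSON sidecar
#'
#' @param truth The `truth` element returned by
#'   [generate_unpaired_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(informative_rna = truth$informative_rna,
         informative_meth = truth$informative_meth,
         labels_rna = truth$labels_rna, labels_meth = truth$labels_meth),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}
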