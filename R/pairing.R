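# Intra-label combinatorial pairing of two unpaired cohorts, with
# leakage-free sample-level splits. A "pair" joins one expression sample
# and one methylation sample carrying the same diagnostic label; the
# Cartesian product of same-label subsets turns two unpaired cohorts into
# a pair-level training corpus. All splitting is done on samples, per
# modality, before any pairing, so no sample contributes to both sides of
# a split.

#' Partition a cohort's samples by label
#'
#' @param x An [omics_matrix].
#' @return A list with character vectors `case` and `control` of sample
#'   IDs; together they partition the cohort.
#' @export
split_by_label <- function(x) {
  ids <- rownames(x$values)
  out <- list(case = ids[x$labels == 1L], control = ids[x$labels == 0L])
  if (length(out$case) == 0L || length(out$control) == 0L)
    stop("both classes must be present")
  out
}

#' Stratified sample-level train/test split
#'
#' Splits each class at `test_fraction` (test size = round(fraction x
#' class size), at least 1), deterministically in `seed`.
#'
#' @param x An [omics_matrix].
#' @param test_fraction Fraction of each class assigned to the test side.
#' @param seed Integer seed.
#' @return A list with `train` and `test` sample-ID vectors plus the
#'   `seed` and `test_fraction` used.
#' @export
stratified_split <- function(x, test_fraction = 0.2, seed = 1L) {
  by_lab <- split_by_label(x)
  with_seed(seed, {
    test <- character(0)
    for (grp in by_lab) {
      n_test <- max(1L, round(test_fraction * length(grp)))
      if (n_test >= length(grp))
        stop("class too small to place at least one sample on each side")
      test <- c(test, sample(grp, n_test))
    }
    train <- setdiff(rownames(x$values), test)
    list(train = train, test = test,
         seed = seed, test_fraction = test_fraction)
  })
}

#' Stratified k-fold partition of a cohort's samples
#'
#' @param x An [omics_matrix].
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return A list of `folds` character vectors of sample IDs; the vectors
#'   are pairwise disjoint and their union is the cohort.
#' @export
stratified_folds <- function(x, folds = 5L, seed = 1L) {
  by_lab <- split_by_label(x)
  if (min(lengths(by_lab)) < folds)
    stop("class too small for the requested number of folds")
  with_seed(seed, {
    assign_folds <- function(ids) {
      ids <- sample(ids)
      split(ids, rep_len(seq_len(folds), length(ids)))
    }
    fc <- assign_folds(by_lab$case)
    fk <- assign_folds(by_lab$control)
    lapply(seq_len(folds), function(i) c(fc[[i]], fk[[i]]))
  })
}

new_pairing_plan <- function(rna_id, meth_id, label, role = "train") {
  df <- data.frame(rna_id = as.character(rna_id),
                   meth_id = as.character(meth_id),
                   label = as.integer(label),
                   role = rep_len(role, length(rna_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("pairing_plan", class(df))
  df
}

#' Enumerate all intra-label pairs between two same-label subsets
#'
#' Forms the full Cartesian product of an expression-sample subset and a
#' methylation-sample subset sharing one label: the pair count is the
#' product of the subset sizes.
#'
#' @param rna_ids,meth_ids Character vectors of sample IDs.
#' @param label The shared label (0 or 1).
#' @param rna_labels,meth_labels Optional named label vectors used to
#'   verify that every sample carries `label`.
#' @param role `"train"` or `"test"` tag recorded on the plan.
#' @return A `pairing_plan` data frame with columns `rna_id`, `meth_id`,
#'   `label`, `role`.
#' @export
enumerate_pairs <- function(rna_ids, meth_ids, label,
                            rna_labels = NULL, meth_labels = NULL,
                            role = "train") {
  if (!is.null(rna_labels) && any(rna_labels[rna_ids] != label))
    stop("label mismatch in the expression subset")
  if (!is.null(meth_labels) && any(meth_labels[meth_ids] != label))
    stop("label mismatch in the methylation subset")
  if (length(rna_ids) == 0L || length(meth_ids) == 0L)
    return(new_pairing_plan(character(0), character(0), integer(0), role))
  grid <- expand.grid(meth_id = meth_ids, rna_id = rna_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  new_pairing_plan(grid$rna_id, grid$meth_id, label, role)
}

# All intra-label pairs between given sample sets of the two cohorts.
enumerate_all_pairs <- function(rna, meth, rna_ids = NULL, meth_ids = NULL,
                                role = "train") {
  if (is.null(rna_ids)) rna_ids <- rownames(rna$values)
  if (is.null(meth_ids)) meth_ids <- rownames(meth$values)
  rl <- stats::setNames(rna$labels, rownames(rna$values))
  ml <- stats::setNames(meth$labels, rownames(meth$values))
  plans <- lapply(c(1L, 0L), function(lab) {
    enumerate_pairs(rna_ids[rl[rna_ids] == lab], meth_ids[ml[meth_ids] == lab],
                    lab, role = role)
  })
  out <- do.call(rbind, plans)
  class(out) <- c("pairing_plan", "data.frame")
  out
}

#' Sample one label-consistent training mini-batch
#'
#' Draws `rna_per_batch` expression samples without replacement (within
#' the batch) and pairs each with `meth_per_rna` same-label methylation
#' samples drawn without replacement per expression sample. Across
#' batches, samples may recur.
#'
#' @param rna_ids Candidate expression sample IDs.
#' @param rna_labels Named label vector for the expression cohort.
#' @param meth_by_label List with `case`/`control` methylation sample IDs.
#' @param rna_per_batch Number of expression samples per batch.
#' @param meth_per_rna Methylation samples paired with each expression
#'   sample.
#' @return A `pairing_plan` with `rna_per_batch * meth_per_rna` rows.
#' @export
sample_minibatch <- function(rna_ids, rna_labels, meth_by_label,
                             rna_per_batch = 32L, meth_per_rna = 2L) {
  if (rna_per_batch > length(rna_ids))
    stop("rna_per_batch exceeds the available expression samples")
  if (meth_per_rna > min(lengths(meth_by_label)))
    stop("meth_per_rna exceeds the available methylation samples")
  chosen <- sample(rna_ids, rna_per_batch)
  rna_rep <- rep(chosen, each = meth_per_rna)
  meth_sel <- unlist(lapply(chosen, function(sid) {
    pool <- if (rna_labels[[sid]] == 1L) meth_by_label$case
            else meth_by_label$control
    pool[sample.int(length(pool), meth_per_rna)]
  }), use.names = FALSE)
  new_pairing_plan(rna_rep, meth_sel, rna_labels[rna_rep])
}

#' Write a pairing plan as TSV
#' @param plan A `pairing_plan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairing_plan <- function(plan, path) {
  utils::write.table(plan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
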