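# Probe-level to gene-level preprocessing: probe collapse, TSS-window CpG
# mapping, missingness filtering with zero imputation, cross-modality
# feature intersection and scaling.

#' Build a probe annotation table
#'
#' @param probe_id Character vector of probe identifiers (unique).
#' @param gene_symbol Character vector of gene symbols; `NA` marks probes
#'   without a clear gene annotation. A probe annotated to more than one
#'   gene appears on multiple rows.
#' @param tss_offset Optional signed distance to the transcription start
#'   site in base pairs; negative values are upstream of the TSS.
#' @return A `data.frame` with columns `probe_id`, `gene_symbol` and
#'   (optionally) `tss_offset`.
#' @export
probe_annotation <- function(probe_id, gene_symbol, tss_offset = NULL) {
  df <- data.frame(probe_id = as.character(probe_id),
                   gene_symbol = as.character(gene_symbol),
                   stringsAsFactors = FALSE)
  if (!is.null(tss_offset)) df$tss_offset <- as.numeric(tss_offset)
  if (anyDuplicated(df)) stop("duplicated annotation rows")
  df
}

#' Read a probe annotation table from TSV
#'
#' Expects columns `probe_id`, `gene_symbol` and optionally `tss_offset`;
#' empty `gene_symbol` fields are read as missing.
#' @param path Input file path.
#' @return A probe annotation `data.frame`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% colnames(df)))
    stop("annotation must have 'probe_id' and 'gene_symbol' columns")
  df
}

# Mean of the observed probe values of each gene, per sample. Probes whose
# values are all missing for a sample yield a missing gene value.
probe_means_by_gene <- function(values, probe_gene) {
  genes <- sort(unique(probe_gene))
  out <- matrix(NA_real_, nrow(values), length(genes),
                dimnames = list(rownames(values), genes))
  for (g in seq_along(genes)) {
    cols <- which(probe_gene == genes[g])
    block <- values[, cols, drop = FALSE]
    obs <- rowSums(!is.na(block))
    m <- rowMeans(block, na.rm = TRUE)
    m[obs == 0L] <- NA_real_
    out[, g] <- m
  }
  out
}

#' Collapse probe-level features to gene symbols
#'
#' Probes mapping to the same gene are averaged arithmetically per sample,
#' with missing values excluded from the mean (a gene whose probes are all
#' missing in a sample stays missing). Probes without a gene annotation
#' are discarded.
#'
#' @param x An [omics_matrix] whose features are probe IDs.
#' @param annotation A probe annotation table ([probe_annotation()]).
#' @return An `omics_matrix` with gene symbols as features.
#' @export
collapse_probes <- function(x, annotation) {
  ann <- annotation[!is.na(annotation$gene_symbol), , drop = FALSE]
  ann <- ann[ann$probe_id %in% colnames(x$values), , drop = FALSE]
  if (nrow(ann) == 0L) stop("no probes mappable")
  vals <- x$values[, ann$probe_id, drop = FALSE]
  out <- probe_means_by_gene(vals, ann$gene_symbol)
  omics_matrix(out, rownames(out), colnames(out), x$labels, x$modality)
}

#' Map CpG probes to genes through an upstream TSS window
#'
#' Keeps CpG probes lying within `window_bp` base pairs upstream of a
#' transcription start site (offsets in \[-window_bp, 0\], negative =
#' upstream), drops probes annotated to more than one gene (ambiguous),
#' and averages the retained probes per gene and sample.
#'
#' @param x A methylation [omics_matrix] with probe-level features.
#' @param annotation Annotation table with `tss_offset` present.
#' @param window_bp Window size in base pairs upstream of the TSS.
#' @return An `omics_matrix` of gene-level beta values.
#' @export
map_cpg_to_genes <- function(x, annotation, window_bp = 1500) {
  if (x$modality != "methylation")
    stop("map_cpg_to_genes expects a methylation matrix")
  if (is.null(annotation$tss_offset))
    stop("annotation must carry 'tss_offset' for CpG mapping")
  ann <- annotation[!is.na(annotation$gene_symbol) &
                      !is.na(annotation$tss_offset), , drop = FALSE]
  ambiguous <- unique(ann$probe_id[duplicated(ann$probe_id)])
  ann <- ann[!(ann$probe_id %in% ambiguous), , drop = FALSE]
  ann <- ann[ann$tss_offset >= -window_bp & ann$tss_offset <= 0, , drop = FALSE]
  ann <- ann[ann$probe_id %in% colnames(x$values), , drop = FALSE]
  if (nrow(ann) == 0L) stop("no CpG probes within the TSS window")
  vals <- x$values[, ann$probe_id, drop = FALSE]
  out <- probe_means_by_gene(vals, ann$gene_symbol)
  omics_matrix(out, rownames(out), colnames(out), x$labels, x$modality)
}

#' Drop high-missingness features and zero-impute the rest
#'
#' Features whose missing fraction strictly exceeds
#' `max_missing_fraction` are removed; every remaining missing entry is
#' set to exactly 0, so the output contains no missing values.
#'
#' @param x An [omics_matrix].
#' @param max_missing_fraction Missingness threshold (default 0.30).
#' @return The filtered, imputed matrix.
#' @export
filter_missing <- function(x, max_missing_fraction = 0.30) {
  frac <- colMeans(is.na(x$values))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("all features exceed the missingness threshold")
  v <- x$values[, keep, drop = FALSE]
  v[is.na(v)] <- 0
  omics_matrix(v, rownames(v), colnames(v), x$labels, x$modality)
}

#' Restrict two gene-level matrices to their common genes
#'
#' Both outputs carry exactly the intersection of the two gene sets, in
#' lexicographic column order.
#'
#' @param rna,meth Gene-level [omics_matrix] objects.
#' @return A list with the restricted `rna` and `meth` matrices.
#' @export
intersect_features <- function(rna, meth) {
  common <- sort(intersect(colnames(rna$values), colnames(meth$values)))
  if (length(common) == 0L) stop("no common features between modalities")
  list(rna = om_subset(rna, features = common),
       meth = om_subset(meth, features = common))
}

#' Per-feature z-scoring with reusable statistics
#'
#' When `stats` is `NULL` the per-feature mean and standard deviation are
#' estimated from `x` and returned alongside the transformed matrix (the
#' training-set path); otherwise the supplied statistics are applied
#' unchanged (the test-set path). Zero-variance features are scaled by 1.
#'
#' @param x An [omics_matrix] without missing entries.
#' @param stats Optional list with `center` and `scale` vectors.
#' @return A list with the transformed numeric `values` matrix (z-scores
#'   are unbounded, so it is returned as a plain matrix) and the `stats`
#'   used.
#' @export
standardize_features <- function(x, stats = NULL) {
  if (anyNA(x$values)) stop("standardize_features requires no missing entries")
  if (is.null(stats)) {
    center <- colMeans(x$values)
    scale_ <- apply(x$values, 2L, stats::sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    stats <- list(center = center, scale = scale_)
  }
  v <- sweep(sweep(x$values, 2L, stats$center), 2L, stats$scale, "/")
  list(values = v, stats = stats)
}

#' Min-max rescaling to the unit interval with reusable statistics
#'
#' Maps each feature onto \[0, 1\] using per-feature minima and ranges,
#' clipping out-of-range test values. This is the scaling used in front of
#' the network, whose reconstruction decoders terminate in a sigmoid.
#'
#' @param x An [omics_matrix] without missing entries.
#' @param stats Optional list with `min` and `range` vectors (training
#'   statistics to reuse).
#' @return A list with the rescaled `matrix` (numeric) and `stats`.
#' @export
rescale_unit <- function(x, stats = NULL) {
  if (anyNA(x$values)) stop("rescale_unit requires no missing entries")
  if (is.null(stats)) {
    mn <- apply(x$values, 2L, min)
    rg <- apply(x$values, 2L, max) - mn
    rg[rg == 0] <- 1
    stats <- list(min = mn, range = rg)
  }
  v <- sweep(sweep(x$values, 2L, stats$min), 2L, stats$range, "/")
  v[v < 0] <- 0
  v[v > 1] <- 1
  list(values = v, stats = stats)
}

#' Per-batch mean-centering hook
#'
#' A pluggable, deliberately simple batch-adjustment default: each
#' feature is centered within each batch and the global feature mean is
#' added back. A different adjuster can be supplied via `fun`.
#'
#' @param x An [omics_matrix] without missing entries.
#' @param batch Factor or character vector of batch labels per sample.
#' @param fun Optional replacement function `(values, batch) -> values`.
#' @return The adjusted `omics_matrix`.
#' @export
adjust_batches <- function(x, batch, fun = NULL) {
  if (anyNA(x$values)) stop("adjust_batches requires no missing entries")
  if (length(batch) != nrow(x$values))
    stop("batch length must equal the number of samples")
  v <- x$values
  if (!is.null(fun)) {
    v <- fun(v, batch)
  } else {
    gm <- colMeans(v)
    for (b in unique(batch)) {
      idx <- which(batch == b)
      v[idx, ] <- sweep(v[idx, , drop = FALSE], 2L,
                        colMeans(v[idx, , drop = FALSE]) - gm)
    }
  }
  omics_matrix(v, rownames(x$values), colnames(x$values), x$labels, x$modality)
}
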