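#' Samples-by-features omics matrix with labels
#'
#' The basic data container: a numeric samples x features matrix (`NA`
#' entries mark missing measurements), unique sample and feature
#' identifiers, a binary case/control label per sample (1 = case,
#' 0 = control) and a modality tag. Methylation values are beta values and
#' every observed entry must lie in \[0, 1\].
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param feature_ids Character vector of unique feature identifiers
#'   (probe IDs or gene symbols).
#' @param labels Integer/numeric vector of 0/1 labels, one per sample.
#' @param modality `"expression"` or `"methylation"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, sample_ids, feature_ids, labels,
                         modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must equal the number of rows")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length must equal the number of columns")
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (anyDuplicated(feature_ids)) stop("duplicate feature IDs")
  if (length(labels) != nrow(values))
    stop("labels length must equal the number of samples")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (modality == "methylation") {
    obs <- values[!is.na(values)]
    if (length(obs) && (min(obs) < 0 || max(obs) > 1))
      stop("methylation values must lie in [0, 1]")
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_ids))
  structure(
    list(values = values, labels = labels, modality = modality),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix: %s, %d samples x %d features, %d case / %d control, %.1f%% missing>\n",
    x$modality, nrow(x$values), ncol(x$values),
    sum(x$labels == 1L), sum(x$labels == 0L),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)

# Subset by sample IDs (rows) and/or feature IDs (columns).
om_subset <- function(x, samples = NULL, features = NULL) {
  v <- x$values
  lab <- x$labels
  if (!is.null(samples)) {
    idx <- match(samples, rownames(v))
    if (anyNA(idx)) stop("unknown sample IDs in subset")
    v <- v[idx, , drop = FALSE]
    lab <- lab[idx]
  }
  if (!is.null(features)) {
    jdx <- match(features, colnames(v))
    if (anyNA(jdx)) stop("unknown feature IDs in subset")
    v <- v[, jdx, drop = FALSE]
  }
  omics_matrix(v, rownames(v), colnames(v), lab, x$modality)
}

#' Write an omics matrix as tab-separated text
#'
#' Layout: first column `sample_id`, second column `label`, remaining
#' columns one per feature; missing entries are written as empty fields.
#'
#' @param x An `omics_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_omics_tsv <- function(x, path) {
  df <- data.frame(
    sample_id = rownames(x$values),
    label = x$labels,
    as.data.frame(x$values, check.names = FALSE),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an omics matrix from delimited text
#'
#' Accepts the layout written by [write_omics_tsv()]; the delimiter (tab
#' or comma) is auto-detected from the header line. Empty fields become
#' missing values.
#'
#' @param path Input file path.
#' @param modality Modality tag to attach.
#' @return An `omics_matrix`.
#' @export
read_omics_delim <- function(path, modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, na.strings = "",
                          colClasses = NA, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(df)))
    stop("expected 'sample_id' and 'label' columns in ", path)
  feat <- setdiff(colnames(df), c("sample_id", "label"))
  vals <- as.matrix(df[, feat, drop = FALSE])
  storage.mode(vals) <- "double"
  omics_matrix(vals, df$sample_id, feat, df$label, modality)
}
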