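#' Count matrix with sample metadata
#'
#' The basic container of the package: a genes-by-samples matrix of
#' non-negative integer counts together with a sample metadata table. Counts
#' are rounded to integers on construction (pseudo-alignment estimates are
#' fractional). Metadata rows are matched to count columns by `sample_id`.
#'
#' @param counts numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids). Values must be non-negative; they are rounded
#'   to integers.
#' @param meta data.frame with one row per sample and at least the columns
#'   `sample_id`, `timepoint_hpf`, `protocol` (`"polyA"` or `"ribo"`),
#'   `condition` (`"untreated"`, `"dmso"` or `"triptolide"`) and `replicate`.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   and `meta`.
#' @export
count_matrix <- function(counts, meta) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have gene-id rownames and sample-id colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("gene ids must be unique")
  if (any(counts < 0) || any(!is.finite(counts)))
    stopf("counts must be finite and non-negative")
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  need <- c("sample_id", "timepoint_hpf", "protocol", "condition", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("metadata lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (!setequal(meta$sample_id, colnames(counts)) ||
      nrow(meta) != ncol(counts))
    stopf("metadata rows must match count columns one-to-one by sample_id")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  bad <- setdiff(unique(meta$protocol), c("polyA", "ribo"))
  if (length(bad)) stopf("unknown protocol: %s", paste(bad, collapse = ", "))
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  protocols: %s | conditions: %s | timepoints: %s\n",
              paste(unique(x$meta$protocol), collapse = ","),
              paste(unique(x$meta$condition), collapse = ","),
              paste(sort(unique(x$meta$timepoint_hpf)), collapse = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Select samples of a count matrix by metadata
#'
#' @param cm a [count_matrix()].
#' @param protocol,condition,timepoint optional filters; `NULL` keeps all.
#' @param genes optional character vector of gene ids to keep.
#' @return a `count_matrix` restricted to the matching samples/genes.
#' @export
cm_select <- function(cm, protocol = NULL, condition = NULL, timepoint = NULL,
                      genes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rep(TRUE, nrow(cm$meta))
  if (!is.null(protocol)) keep <- keep & cm$meta$protocol %in% protocol
  if (!is.null(condition)) keep <- keep & cm$meta$condition %in% condition
  if (!is.null(timepoint)) keep <- keep & cm$meta$timepoint_hpf %in% timepoint
  if (!any(keep)) stopf("no samples match the requested selection")
  g <- if (is.null(genes)) rownames(cm$counts) else genes
  count_matrix(cm$counts[g, keep, drop = FALSE],
               cm$meta[keep, , drop = FALSE])
}

#' Sample ids matching metadata filters
#'
#' @inheritParams cm_select
#' @return character vector of sample ids.
#' @export
cm_samples <- function(cm, protocol = NULL, condition = NULL,
                       timepoint = NULL) {
  keep <- rep(TRUE, nrow(cm$meta))
  if (!is.null(protocol)) keep <- keep & cm$meta$protocol %in% protocol
  if (!is.null(condition)) keep <- keep & cm$meta$condition %in% condition
  if (!is.null(timepoint)) keep <- keep & cm$meta$timepoint_hpf %in% timepoint
  cm$meta$sample_id[keep]
}

#' Read/write a count matrix as TSV
#'
#' Counts are stored as a TSV with a `gene_id` column followed by one column
#' per sample; metadata as a separate TSV.
#'
#' @param counts_path,meta_path file paths.
#' @param cm a [count_matrix()].
#' @return `read_count_matrix()` returns a `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  tab <- read_tsv(counts_path)
  meta <- read_tsv(meta_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  count_matrix(m, meta)
}

#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(cm, counts_path, meta_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(cm$meta, meta_path)
  invisible(c(counts_path, meta_path))
}

# mean count/TPM columns per timepoint for one protocol+condition
by_time <- function(mat, meta, protocol = NULL, condition = "untreated") {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(protocol)) keep <- keep & meta$protocol %in% protocol
  if (!is.null(condition)) keep <- keep & meta$condition %in% condition
  meta <- meta[keep, , drop = FALSE]
  mat <- mat[, meta$sample_id, drop = FALSE]
  tps <- sort(unique(meta$timepoint_hpf))
  out <- sapply(tps, function(t)
    rowMeans(mat[, meta$sample_id[meta$timepoint_hpf == t], drop = FALSE]))
  colnames(out) <- as.character(tps)
  out
}

#' Average expression per timepoint
#'
#' Collapses replicate columns of a TPM (or count) matrix to per-timepoint
#' means for one protocol and condition.
#'
#' @param mat genes x samples matrix (e.g. from [compute_tpm()]).
#' @param cm the [count_matrix()] the columns belong to (supplies metadata).
#' @param protocol,condition metadata filters.
#' @return genes x timepoints matrix; column names are the timepoints.
#' @export
expression_by_time <- function(mat, cm, protocol = NULL,
                               condition = "untreated") {
  by_time(mat, cm$meta, protocol, condition)
}
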