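# Histone-centric metrics: transcriptome share per histone class and the
# cross-species style "net activation" trajectory with optional trimmed
# normalization.

#' Transcriptome proportions per gene class
#'
#' Share of total TPM carried by each class at each timepoint (replicate
#' means). Genes absent from the class map count as `non_histone`; shares sum
#' to 1 at every timepoint.
#'
#' @param tpm genes x samples TPM matrix.
#' @param cm [count_matrix()] supplying metadata.
#' @param class_map data.frame with `gene_id` and `class` columns.
#' @param protocol,condition sample filters (histone quantification requires
#'   the rRNA-depleted protocol since replication-dependent histone mRNA are
#'   not polyadenylated; the default follows that).
#' @return data.frame `timepoint` x `class` with a `proportion` column.
#' @export
class_proportions <- function(tpm, cm, class_map, protocol = "ribo",
                              condition = "untreated") {
  bt <- expression_by_time(tpm, cm, protocol = protocol,
                           condition = condition)
  cls <- setNames(class_map$class, class_map$gene_id)
  gene_class <- cls[rownames(bt)]
  gene_class[is.na(gene_class)] <- "non_histone"
  tot <- colSums(bt)
  out <- do.call(rbind, lapply(colnames(bt), function(tn) {
    s <- tapply(bt[, tn], gene_class, sum)
    data.frame(timepoint = as.numeric(tn), class = names(s),
               proportion = as.numeric(s) / tot[tn])
  }))
  rownames(out) <- NULL
  out
}

#' Net activation over baseline per gene class
#'
#' Per gene, expression increase in reads per million over a baseline
#' (default: the maximum of the first two timepoints, which precede genome
#' activation; `baseline = "first"` uses only the first, the convention
#' needed when the second timepoint already post-dates activation). A gene
#' contributes at a timepoint only while its RPM is at least `fold_min` times
#' the baseline (inclusive); contributions are summed within class. With
#' `trimmed = TRUE` the RPM denominator is the summed counts of genes whose
#' totals lie within the `trim` percentile band, which keeps a handful of
#' extremely high-count genes (histones) from deflating everyone else's RPM.
#'
#' @param counts genes x samples count matrix (or [count_matrix()]).
#' @param cm [count_matrix()] supplying metadata (ignored if `counts` is one).
#' @param class_map data.frame with `gene_id`, `class`; unmapped genes count
#'   as `non_histone`.
#' @param baseline `"max2"` (default) or `"first"`.
#' @param fold_min inclusion gate (default 2), evaluated per timepoint.
#' @param trimmed use the trimmed library-size denominator.
#' @param trim inclusive percentile band for trimming (default 10th-90th).
#' @param protocol,condition sample filters.
#' @return data.frame `timepoint` x `class` with `net_rpm`.
#' @export
net_activation <- function(counts, cm = NULL, class_map,
                           baseline = c("max2", "first"), fold_min = 2,
                           trimmed = FALSE, trim = c(0.1, 0.9),
                           protocol = "ribo", condition = "untreated") {
  baseline <- match.arg(baseline)
  if (fold_min < 1) stopf("fold_min must be >= 1")
  if (inherits(counts, "count_matrix")) {
    cm <- counts
    counts <- counts$counts
  }
  meta <- cm$meta
  keep <- meta$protocol %in% protocol & meta$condition %in% condition
  meta <- meta[keep, , drop = FALSE]
  m <- counts[, meta$sample_id, drop = FALSE]
  denom <- if (trimmed) {
    tot <- rowSums(m)
    qs <- quantile(tot, trim, type = 7)
    inband <- tot >= qs[1] & tot <= qs[2]
    colSums(m[inband, , drop = FALSE])
  } else colSums(m)
  rpm <- sweep(m, 2, denom / 1e6, "/")
  bt <- by_time(rpm, meta)
  if (ncol(bt) < 2 && baseline == "max2")
    stopf("baseline 'max2' needs at least two timepoints")
  base <- if (baseline == "max2")
    pmax(bt[, 1], bt[, 2]) else bt[, 1]
  cls <- setNames(class_map$class, class_map$gene_id)
  gene_class <- cls[rownames(bt)]
  gene_class[is.na(gene_class)] <- "non_histone"
  out <- do.call(rbind, lapply(colnames(bt), function(tn) {
    x <- bt[, tn]
    inc <- ifelse(x >= fold_min * base, x - base, 0)
    s <- tapply(inc, gene_class, sum)
    data.frame(timepoint = as.numeric(tn), class = names(s),
               net_rpm = as.numeric(s))
  }))
  rownames(out) <- NULL
  out
}
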