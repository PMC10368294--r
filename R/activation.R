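# Zygotic genome activation calling: exonic activation thresholds, intron
# count construction with the intronic-RPKM gate, combined exon+intron
# testing for re-activated maternal genes, per-gene categorization, and the
# 10-kb window scan for unannotated activation.

#' Differential expression series against the egg
#'
#' Runs [nb_test()] for each later timepoint against the first (egg)
#' timepoint within one condition, the contrast pattern used by activation
#' and clearance calling.
#'
#' @param cm a [count_matrix()] (one protocol, or mixed; filter first).
#' @param condition condition to test within.
#' @param ref_time reference (egg) timepoint; defaults to the earliest.
#' @param times timepoints to contrast; defaults to all later ones.
#' @param ... passed to [nb_test()].
#' @return named list of [nb_test()] results, keyed by timepoint.
#' @export
de_series <- function(cm, condition = "untreated", ref_time = NULL,
                      times = NULL, ...) {
  meta <- cm$meta[cm$meta$condition == condition, , drop = FALSE]
  tps <- sort(unique(meta$timepoint_hpf))
  if (is.null(ref_time)) ref_time <- tps[1]
  if (is.null(times)) times <- tps[tps > ref_time]
  ref <- meta$sample_id[meta$timepoint_hpf == ref_time]
  if (!length(ref)) stopf("no samples at the reference timepoint")
  out <- lapply(times, function(t) {
    nb_test(cm, ref, meta$sample_id[meta$timepoint_hpf == t], ...)
  })
  names(out) <- as.character(times)
  out
}

#' Intron count table with the intronic-RPKM gate
#'
#' Intron counts are pre-mRNA counts minus exon counts, clamped at zero
#' (counting noise can push exon above pre-mRNA at the count-table level; the
#' number of clamped cells is reported). Intronic RPKM uses the gene's summed
#' intron length as length factor and the sample's summed pre-mRNA counts as
#' library factor. Intronless genes are excluded, as are genes whose intronic
#' RPKM stays below `rpkm_min` in every sample (a single passing sample keeps
#' the gene testable).
#'
#' @param premrna,exon [count_matrix()] objects over the same genes and
#'   samples (rRNA-depleted libraries).
#' @param models a [gene_models()] object supplying intron lengths.
#' @param rpkm_min intronic RPKM threshold (default 0.5).
#' @return list of class `intron_counts`: `counts` (intron count matrix over
#'   retained genes), `rpkm`, `meta`, `clamped` (number of clamped cells),
#'   `excluded_intronless`, `excluded_low_rpkm`.
#' @export
build_intron_counts <- function(premrna, exon, models, rpkm_min = 0.5) {
  if (!identical(colnames(premrna$counts), colnames(exon$counts)))
    stopf("pre-mRNA and exon tables must cover the same samples")
  common <- intersect(rownames(premrna$counts), rownames(exon$counts))
  if (!length(common)) stopf("no shared genes between tables")
  p <- premrna$counts[common, , drop = FALSE]
  e <- exon$counts[common, , drop = FALSE]
  raw <- p - e
  clamped <- sum(raw < 0)
  if (clamped > 0)
    message(sprintf("build_intron_counts: clamped %d negative cell(s) to 0",
                    clamped))
  intron <- pmax(raw, 0)
  il <- setNames(models$genes$intron_bp, models$genes$gene_id)[common]
  il[is.na(il)] <- 0
  has_intron <- il > 0
  lib <- colSums(p)
  rpkm <- sweep(sweep(intron, 1, pmax(il, 1) / 1e3, "/"), 2, lib / 1e6, "/")
  pass <- has_intron & (rowSums(rpkm >= rpkm_min) > 0)
  structure(list(
    counts = intron[pass, , drop = FALSE],
    rpkm = rpkm[pass, , drop = FALSE],
    meta = premrna$meta,
    clamped = clamped,
    excluded_intronless = sum(!has_intron),
    excluded_low_rpkm = sum(has_intron & !pass)),
    class = "intron_counts")
}

#' @export
print.intron_counts <- function(x, ...) {
  cat(sprintf(
    "intron_counts: %d genes retained (%d intronless, %d below RPKM gate)\n",
    nrow(x$counts), x$excluded_intronless, x$excluded_low_rpkm))
  invisible(x)
}

#' Combined exon + intron count matrix
#'
#' Stacks exon and intron entries (`gene@exon`, `gene@intron`) into one
#' [count_matrix()] so a single differential test adjusts the two entry types
#' jointly.
#'
#' @param exon exon-level [count_matrix()].
#' @param intron an [build_intron_counts()] result.
#' @return a [count_matrix()] with two entries per intron-testable gene.
#' @export
combine_exon_intron <- function(exon, intron) {
  stopifnot(inherits(intron, "intron_counts"))
  if (!identical(colnames(exon$counts), colnames(intron$counts)))
    stopf("exon and intron tables must cover the same samples")
  ex <- exon$counts
  rownames(ex) <- paste0(rownames(ex), "@exon")
  inm <- intron$counts
  rownames(inm) <- paste0(rownames(inm), "@intron")
  count_matrix(rbind(ex, inm), exon$meta)
}

#' Call exonic activation
#'
#' A gene is called activated at timepoint `t` when, in the rRNA-depleted
#' contrast of `t` against egg, the adjusted p-value is below `padj_max`, the
#' upward fold change strictly exceeds `fold_min`, and its expression at `t`
#' exceeds `tpm_min` TPM. Calling on poly(A)+ contrasts is refused: tail
#' dynamics confound activation there.
#'
#' @param de_by_time list of [nb_test()] results keyed by timepoint (from
#'   [de_series()] on rRNA-depleted samples).
#' @param tpm_by_time genes x timepoints TPM matrix (see
#'   [expression_by_time()]).
#' @param fold_min,padj_max,tpm_min thresholds (defaults 2, 0.05, 1).
#' @return data.frame with `gene_id`, `timepoint`, `evidence = "exon"`.
#' @export
call_exonic_activation <- function(de_by_time, tpm_by_time, fold_min = 2,
                                   padj_max = 0.05, tpm_min = 1) {
  rows <- lapply(names(de_by_time), function(tn) {
    de <- de_by_time[[tn]]
    prot <- attr(de, "protocol")
    if (!is.null(prot) && prot != "ribo")
      stopf("activation calls require the rRNA-depleted (ribo) protocol")
    ok <- !de$filtered & !is.na(de$padj) & de$padj < padj_max &
      de$log2FoldChange > log2(fold_min)
    g <- de$gene_id[ok]
    if (length(g) && tn %in% colnames(tpm_by_time)) {
      tv <- rep(Inf, length(g))
      known <- g %in% rownames(tpm_by_time)
      tv[known] <- tpm_by_time[g[known], tn]
      g <- g[tv > tpm_min]
    }
    if (!length(g)) return(NULL)
    data.frame(gene_id = g, timepoint = as.numeric(tn), evidence = "exon")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), timepoint = numeric(0),
                      evidence = character(0))
  out
}

#' Call intron-based (re-)activation
#'
#' Run on a combined exon+intron matrix (see [combine_exon_intron()]): a gene
#' is intron-activated at `t` when its `@intron` entry is significantly up
#' (adjusted p below `padj_max`, positive fold). The BH adjustment inside
#' [nb_test()] spans both entry types of the combined table.
#'
#' @param de_by_time list of [nb_test()] results on the combined matrix,
#'   keyed by timepoint.
#' @param padj_max adjusted-p threshold (default 0.05).
#' @return data.frame with `gene_id`, `timepoint`, `evidence = "intron"`.
#' @export
call_intron_activation <- function(de_by_time, padj_max = 0.05) {
  rows <- lapply(names(de_by_time), function(tn) {
    de <- de_by_time[[tn]]
    isin <- grepl("@intron$", de$gene_id)
    ok <- isin & !de$filtered & !is.na(de$padj) & de$padj < padj_max &
      de$log2FoldChange > 0
    if (!any(ok)) return(NULL)
    data.frame(gene_id = sub("@intron$", "", de$gene_id[ok]),
               timepoint = as.numeric(tn), evidence = "intron")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), timepoint = numeric(0),
                      evidence = character(0))
  out
}

#' Categorize genes by maternal contribution and activation evidence
#'
#' At each timepoint, using activation evidence accumulated up to and
#' including it:
#' `de_novo_zygotic` egg TPM < 0.5 and activated; `maternal_reactivated`
#' egg TPM >= 1 and activated (exonic or intronic evidence);
#' `ambiguous` egg TPM in `[0.5, 1)` with activation evidence;
#' `maternal_only` egg TPM >= 1, never activated by `t`; `not_expressed`
#' otherwise. Every gene receives exactly one category per timepoint.
#'
#' @param egg_tpm named vector of egg (rRNA-depleted) TPM.
#' @param exon_calls,intron_calls call data.frames (see
#'   [call_exonic_activation()], [call_intron_activation()]).
#' @param timepoints timepoints to categorize at.
#' @return data.frame `gene_id` x `timepoint` with a `category` column.
#' @export
categorize_genes <- function(egg_tpm, exon_calls, intron_calls, timepoints) {
  calls <- rbind(exon_calls[, c("gene_id", "timepoint")],
                 intron_calls[, c("gene_id", "timepoint")])
  genes <- names(egg_tpm)
  first_call <- rep(Inf, length(genes))
  names(first_call) <- genes
  if (nrow(calls)) {
    agg <- tapply(calls$timepoint, calls$gene_id, min)
    first_call[names(agg)] <- agg
  }
  out <- do.call(rbind, lapply(timepoints, function(t) {
    act <- first_call <= t
    cat <- ifelse(act & egg_tpm < 0.5, "de_novo_zygotic",
           ifelse(act & egg_tpm >= 1, "maternal_reactivated",
           ifelse(act, "ambiguous",
           ifelse(egg_tpm >= 1, "maternal_only", "not_expressed"))))
    data.frame(gene_id = genes, timepoint = t, category = unname(cat))
  }))
  rownames(out) <- NULL
  out
}

#' Bin gene-level counts into genomic windows
#'
#' Assigns each gene's counts to the fixed-width window containing its span
#' midpoint; windows tile each scaffold from 0.
#'
#' @param models a [gene_models()] object.
#' @param counts named numeric vector of per-gene counts (one library).
#' @param window_size window width in bp (default 10 kb).
#' @return data.frame `scaffold`, `start`, `end` (0-based half-open),
#'   `count`, `genes` (comma-separated ids).
#' @export
bin_counts_by_window <- function(models, counts, window_size = 1e4) {
  if (window_size <= 0) stopf("window size must be positive")
  g <- models$genes
  cnt <- counts[g$gene_id]
  cnt[is.na(cnt)] <- 0
  mid <- (g$start0 + g$end0) / 2
  win <- floor(mid / window_size)
  key <- paste(g$scaffold, win, sep = ":")
  agg <- tapply(cnt, key, sum)
  gl <- tapply(g$gene_id, key, paste, collapse = ",")
  parts <- strsplit(names(agg), ":", fixed = TRUE)
  data.frame(
    scaffold = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)) * window_size,
    end = (as.numeric(vapply(parts, `[`, "", 2)) + 1) * window_size,
    count = as.numeric(agg), genes = as.character(gl), row.names = NULL)
}

#' Windowed activation scan
#'
#' Per-window log2 fold difference of a timepoint against egg after
#' reads-per-million scaling with a pseudocount:
#' `log2((rpm_t + c) / (rpm_egg + c))`. Windows are returned ranked by fold
#' difference.
#'
#' @param windows_t,windows_egg window tables from [bin_counts_by_window()]
#'   over the same windows.
#' @param pseudocount RPM pseudocount `c` (default 0.5).
#' @return the window table with `rpm_t`, `rpm_egg` and `log2fc`, sorted
#'   decreasing.
#' @export
window_scan <- function(windows_t, windows_egg, pseudocount = 0.5) {
  key <- function(w) paste(w$scaffold, w$start)
  if (!identical(key(windows_t), key(windows_egg)))
    stopf("window tables must cover identical windows")
  rpm_t <- windows_t$count / sum(windows_t$count) * 1e6
  rpm_e <- windows_egg$count / sum(windows_egg$count) * 1e6
  out <- windows_t[, c("scaffold", "start", "end", "genes")]
  out$rpm_t <- rpm_t
  out$rpm_egg <- rpm_e
  out$log2fc <- log2((rpm_t + pseudocount) / (rpm_e + pseudocount))
  out[order(-out$log2fc), ]
}
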