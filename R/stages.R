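# Stage-specific expression calling and GO-term stage enrichment.

#' Call stage-specific genes and their peak stage
#'
#' A gene qualifies when its stage-averaged expression drops below
#' `low_tpm` in at least one stage, exceeds `high_tpm` in another, and it is
#' significantly different from egg at some stage. Qualifying genes are
#' clustered by the stage of maximal mean expression (ties broken toward the
#' earliest stage).
#'
#' @param tpm_by_stage genes x stages matrix of stage-mean TPM; column order
#'   is the temporal order.
#' @param sig_genes character vector of genes significant vs egg at any
#'   stage (adjusted p < 0.05 upstream).
#' @param low_tpm,high_tpm thresholds (defaults 1 and 5).
#' @return data.frame `gene_id`, `qualifies`, `peak_stage`, `min_tpm`,
#'   `max_tpm`, `significant`.
#' @export
call_stage_specific <- function(tpm_by_stage, sig_genes, low_tpm = 1,
                                high_tpm = 5) {
  mn <- apply(tpm_by_stage, 1, min)
  mx <- apply(tpm_by_stage, 1, max)
  sig <- rownames(tpm_by_stage) %in% sig_genes
  qual <- mn < low_tpm & mx > high_tpm & sig
  peak <- colnames(tpm_by_stage)[apply(tpm_by_stage, 1, which.max)]
  data.frame(gene_id = rownames(tpm_by_stage), qualifies = qual,
             peak_stage = ifelse(qual, peak, NA_character_),
             min_tpm = mn, max_tpm = mx, significant = sig,
             row.names = NULL)
}

#' Pool stage clusters
#'
#' Maps fine peak stages onto pooled groups (e.g. merging the 4-7 h.p.f.
#' clusters into one gastrula group when per-stage gene counts are low).
#'
#' @param peak_stage named character vector (gene -> stage).
#' @param pools named list: group name -> character vector of stages.
#' @return named character vector (gene -> group); stages not covered by
#'   `pools` keep their own name.
#' @export
pool_stages <- function(peak_stage, pools) {
  out <- peak_stage
  for (grp in names(pools)) out[peak_stage %in% pools[[grp]]] <- grp
  out
}

#' GO-term enrichment across stage clusters
#'
#' For each GO term, a 2 x k chi-squared test of independence on the counts
#' of annotated versus non-annotated genes across the k stage groups,
#' BH-adjusted over all tested terms. Terms producing a zero expected cell
#' are skipped with a reason (pool categories or drop sparse terms upstream).
#'
#' @param go_map data.frame with `gene_id` and `term` columns.
#' @param clusters named character vector: gene -> stage group (genes absent
#'   from it are ignored).
#' @param min_groups minimal number of groups required (default 5, the
#'   pooled egg/gastrula/larval layout).
#' @return data.frame `term`, `statistic`, `dof`, `pvalue`, `padj`, plus the
#'   skipped terms in attribute `skipped`.
#' @export
go_stage_enrichment <- function(go_map, clusters, min_groups = 5) {
  groups <- sort(unique(clusters))
  if (length(groups) < min_groups)
    stopf("need at least %d stage groups after pooling, got %d",
          min_groups, length(groups))
  genes <- names(clusters)
  group_sizes <- table(factor(clusters, levels = groups))
  go_map <- go_map[go_map$gene_id %in% genes, , drop = FALSE]
  terms <- unique(go_map$term)
  res <- list()
  skipped <- character(0)
  for (tm in terms) {
    ann <- unique(go_map$gene_id[go_map$term == tm])
    n_ann <- table(factor(clusters[ann], levels = groups))
    tab <- rbind(annotated = as.integer(n_ann),
                 not_annotated = as.integer(group_sizes - n_ann))
    ct <- tryCatch(chi2_independence(tab), error = function(e) e)
    if (inherits(ct, "error")) {
      skipped <- c(skipped, tm)
      next
    }
    res[[tm]] <- data.frame(term = tm, statistic = ct$statistic,
                            dof = ct$dof, pvalue = ct$p.value)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(term = character(0), statistic = numeric(0),
                      dof = integer(0), pvalue = numeric(0))
  out$padj <- if (nrow(out)) bh_adjust(out$pvalue) else numeric(0)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Maternal transcription-factor shortlist
#'
#' Reduces manual curation to a filter: genes annotated with the supplied
#' DNA-binding GO terms whose egg expression exceeds a floor and is at least
#' `enrich_min`-fold above their minimum across later stages.
#'
#' @param tpm_by_stage genes x stages matrix (first column = egg).
#' @param go_map data.frame `gene_id`, `term`.
#' @param tf_terms GO terms defining transcription-factor annotation.
#' @param egg_min egg TPM floor (default 50).
#' @param enrich_min fold enrichment of egg over the weakest later stage.
#' @return character vector of gene ids.
#' @export
maternal_tf_candidates <- function(tpm_by_stage, go_map,
                                   tf_terms = c("GO:0003700", "GO:0043565"),
                                   egg_min = 50, enrich_min = 5) {
  tf_genes <- unique(go_map$gene_id[go_map$term %in% tf_terms])
  m <- tpm_by_stage[rownames(tpm_by_stage) %in% tf_genes, , drop = FALSE]
  if (!nrow(m)) return(character(0))
  egg <- m[, 1]
  later_min <- apply(m[, -1, drop = FALSE], 1, min)
  rownames(m)[egg > egg_min & egg >= enrich_min * (later_min + 0.1)]
}
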