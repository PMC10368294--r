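# Maternal clearance analysis: first-decrease timing per protocol, clearance
# grouping with the oscillation filter, the stable maternal reference set,
# and the transcription-dependence (triptolide) tests.

#' First significant decrease per gene
#'
#' Scans the egg-versus-timepoint contrasts in ascending time order and
#' reports the first timepoint with adjusted p below `padj_max` and a
#' decrease of at least `fold_min` (boundary inclusive: a gene exactly 2-fold
#' down counts).
#'
#' @param de_by_time list of [nb_test()] results keyed by timepoint.
#' @param fold_min minimal fold decrease (default 2).
#' @param padj_max adjusted-p threshold (default 0.05).
#' @return named numeric vector of first-decrease timepoints (`NA` = never).
#' @export
first_decrease <- function(de_by_time, fold_min = 2, padj_max = 0.05) {
  tps <- as.numeric(names(de_by_time))
  o <- order(tps)
  genes <- de_by_time[[1]]$gene_id
  out <- rep(NA_real_, length(genes))
  names(out) <- genes
  for (i in o) {
    de <- de_by_time[[i]]
    hit <- !de$filtered & !is.na(de$padj) & de$padj < padj_max &
      de$log2FoldChange <= -log2(fold_min)
    new <- de$gene_id[hit]
    new <- new[is.na(out[new])]
    out[new] <- tps[i]
  }
  out
}

#' Oscillation filter on a TPM trajectory
#'
#' Fails a gene whose expression rises more than `rise_max`-fold between any
#' two consecutive stages (strict: exactly 1.5-fold passes). A pseudocount
#' guards ratios at low expression.
#'
#' @param traj numeric TPM trajectory over ordered timepoints (vector or
#'   genes x timepoints matrix).
#' @param rise_max maximal tolerated stage-to-stage increase (default 1.5).
#' @param pseudo TPM pseudocount (default 0.1).
#' @return logical: `TRUE` = passes (minimal oscillation); vectorized over
#'   matrix rows.
#' @export
oscillation_filter <- function(traj, rise_max = 1.5, pseudo = 0.1) {
  m <- if (is.matrix(traj)) traj else matrix(traj, nrow = 1)
  x <- m + pseudo
  ratio <- x[, -1, drop = FALSE] / x[, -ncol(x), drop = FALSE]
  pass <- rowSums(ratio > rise_max) == 0
  if (!is.matrix(traj)) pass[[1]] else setNames(pass, rownames(m))
}

#' Clearance profiles and grouping
#'
#' Combines the first-decrease timing in both protocols into the per-gene
#' clearance profile. Groups: `excluded_oscillating` (fails
#' [oscillation_filter()] on the poly(A)+ trajectory), `early` (first
#' poly(A)+ decrease at 2-4 h.p.f.), `late` (at/after 5 h.p.f.), `stable`
#' (maternal, no decrease in either protocol), `excluded_insignificant`
#' (anything else, e.g. non-maternal genes or decreases seen only in the
#' rRNA-depleted protocol). `deadenylation_lead` is the rRNA-depleted minus
#' poly(A)+ first-decrease time where both exist: positive values mean tail
#' shortening precedes degradation.
#'
#' @param fd_polya,fd_ribo named first-decrease vectors ([first_decrease()]).
#' @param tpm_polya_by_time genes x timepoints poly(A)+ TPM matrix.
#' @param maternal_genes character vector of genes with a maternal
#'   contribution (e.g. egg TPM >= 1).
#' @param early_range inclusive poly(A)+ timing range of the early group.
#' @return data.frame of class `clearance_profiles`.
#' @export
clearance_profiles <- function(fd_polya, fd_ribo, tpm_polya_by_time,
                               maternal_genes, early_range = c(2, 4)) {
  genes <- union(names(fd_polya), names(fd_ribo))
  fp <- fd_polya[genes]
  fr <- fd_ribo[genes]
  osc <- !oscillation_filter(tpm_polya_by_time[
    intersect(genes, rownames(tpm_polya_by_time)), , drop = FALSE])
  oscv <- setNames(rep(FALSE, length(genes)), genes)
  oscv[names(osc)] <- osc
  maternal <- genes %in% maternal_genes
  group <- ifelse(oscv, "excluded_oscillating",
           ifelse(!is.na(fp) & fp >= early_range[1] & fp <= early_range[2],
                  "early",
           ifelse(!is.na(fp) & fp > early_range[2], "late",
           ifelse(maternal & is.na(fp) & is.na(fr), "stable",
                  "excluded_insignificant"))))
  data.frame(gene_id = genes,
             first_decrease_polya = unname(fp),
             first_decrease_ribo = unname(fr),
             group = unname(group),
             deadenylation_lead = unname(fr - fp),
             row.names = NULL)
}

#' Clearance-timing matrix (poly(A)+ vs rRNA-depleted first decrease)
#'
#' Cell counts of genes by first-decrease timepoint in the poly(A)+ (columns)
#' versus rRNA-depleted (rows) protocol, with a terminal `"7+"`-style bin for
#' genes never decreasing. Genes below the diagonal (poly(A)+ decrease
#' earlier) experienced deadenylation before degradation.
#'
#' @param profiles a [clearance_profiles()] result.
#' @param timepoints timepoints spanned by the scan (for the bin layout).
#' @return table of counts; attribute `below_diagonal_fraction` gives the
#'   fraction of genes with both timings defined or a poly(A)+-only decrease
#'   whose poly(A)+ decrease is strictly earlier.
#' @export
clearance_matrix <- function(profiles, timepoints = 2:7) {
  lab <- function(x) ifelse(is.na(x), "never", as.character(x))
  levs <- c(as.character(timepoints), "never")
  px <- factor(lab(profiles$first_decrease_polya), levels = levs)
  rx <- factor(lab(profiles$first_decrease_ribo), levels = levs)
  tab <- table(ribo = rx, polyA = px)
  both <- !is.na(profiles$first_decrease_polya)
  below <- both & (is.na(profiles$first_decrease_ribo) |
                     profiles$first_decrease_polya <
                       profiles$first_decrease_ribo)
  attr(tab, "below_diagonal_fraction") <-
    if (any(both)) sum(below) / sum(both) else NA_real_
  tab
}

#' Classify the clearance mode of each gene
#'
#' Against-the-truth classification used for validation: `stable` (no
#' decrease in either protocol), `deadenylated_only` (poly(A)+ decrease only),
#' `deadenylated_then_degraded` (both, poly(A)+ strictly earlier), `degraded`
#' (rRNA-depleted decrease not preceded by an earlier poly(A)+ decrease).
#'
#' @param profiles a [clearance_profiles()] result.
#' @return named character vector of modes.
#' @export
classify_clearance_mode <- function(profiles) {
  fp <- profiles$first_decrease_polya
  fr <- profiles$first_decrease_ribo
  mode <- ifelse(is.na(fp) & is.na(fr), "stable",
          ifelse(!is.na(fp) & is.na(fr), "deadenylated_only",
          ifelse(!is.na(fp) & !is.na(fr) & fp < fr,
                 "deadenylated_then_degraded", "degraded")))
  setNames(mode, profiles$gene_id)
}

#' Stable maternal reference set
#'
#' Maternal genes whose poly(A)+ TPM stays within `fold_max`-fold of the egg
#' level (both directions, strict) at every one of `times`, and that are not
#' significantly changed by transcription inhibition (triptolide vs DMSO
#' adjusted p >= `padj_max`; genes prefiltered out of that contrast count as
#' unchanged).
#'
#' @param tpm_polya_by_time genes x timepoints poly(A)+ TPM matrix including
#'   the egg column `"0"`.
#' @param trip_de [nb_test()] result of triptolide vs DMSO.
#' @param maternal_genes genes eligible for the reference set.
#' @param fold_max maximal fold difference (default 1.25, strict).
#' @param times timepoints that must all be stable (default 4:7).
#' @param pseudo TPM pseudocount.
#' @param padj_max significance threshold for the triptolide response.
#' @return character vector of reference gene ids; attributes record the
#'   criteria.
#' @export
stable_reference_set <- function(tpm_polya_by_time, trip_de, maternal_genes,
                                 fold_max = 1.25, times = 4:7, pseudo = 0.1,
                                 padj_max = 0.05) {
  tn <- as.character(times)
  miss <- setdiff(c("0", tn), colnames(tpm_polya_by_time))
  if (length(miss)) stopf("missing timepoint column(s): %s",
                          paste(miss, collapse = ", "))
  m <- tpm_polya_by_time[intersect(maternal_genes,
                                   rownames(tpm_polya_by_time)), ,
                         drop = FALSE]
  ratio <- (m[, tn, drop = FALSE] + pseudo) / (m[, "0"] + pseudo)
  stable <- rowSums(ratio >= fold_max | ratio <= 1 / fold_max) == 0
  sig <- trip_de$gene_id[!is.na(trip_de$padj) & trip_de$padj < padj_max]
  keep <- rownames(m)[stable] |> setdiff(sig)
  structure(keep, criteria = list(fold_max = fold_max, times = times,
                                  padj_max = padj_max, pseudo = pseudo))
}

#' Log2 TPM fold change against egg for one condition
#'
#' @param tpm genes x samples TPM matrix.
#' @param cm the [count_matrix()] supplying metadata.
#' @param condition condition of the later timepoint.
#' @param time later timepoint (default: the last).
#' @param protocol protocol to use.
#' @param pseudo TPM pseudocount (default 0.1).
#' @return named vector of per-gene `log2((tpm_t + c) / (tpm_egg + c))`; egg
#'   is the earliest untreated timepoint of the protocol.
#' @export
tpm_fold_change <- function(tpm, cm, condition, time = NULL,
                            protocol = "ribo", pseudo = 0.1) {
  meta <- cm$meta
  sel <- meta$protocol == protocol
  egg_t <- min(meta$timepoint_hpf[sel & meta$condition == "untreated"])
  if (is.null(time))
    time <- max(meta$timepoint_hpf[sel & meta$condition == condition])
  egg <- rowMeans(tpm[, meta$sample_id[sel & meta$condition == "untreated" &
                                         meta$timepoint_hpf == egg_t],
                      drop = FALSE])
  late <- rowMeans(tpm[, meta$sample_id[sel & meta$condition == condition &
                                          meta$timepoint_hpf == time],
                       drop = FALSE])
  log2((late + pseudo) / (egg + pseudo))
}

#' Transcription dependence of clearance (triptolide effect)
#'
#' For a gene group (early- or late-cleared), compares per-gene fold changes
#' to egg under transcription inhibition against vehicle: paired differences
#' `d_g = FC_triptolide - FC_dmso` are tested with the Wilcoxon signed-rank
#' test. Positive median differences in the rRNA-depleted protocol mean
#' clearance was inhibited (transcripts stabilized), i.e. the clearance of
#' the group is transcription-dependent.
#'
#' @param fc_trip,fc_dmso named vectors of log2 fold changes vs egg (see
#'   [tpm_fold_change()]).
#' @param genes gene ids of the group (must have >= `min_n` members present
#'   in both vectors).
#' @param min_n minimal group size for the test (default 5).
#' @return list with `median_shift`, `p.value`, `direction`
#'   (`"stabilized"`/`"destabilized"`), `n`.
#' @export
triptolide_effect <- function(fc_trip, fc_dmso, genes, min_n = 5) {
  g <- intersect(genes, intersect(names(fc_trip), names(fc_dmso)))
  if (length(g) < min_n)
    stopf("group too small for the paired test (%d < %d)", length(g), min_n)
  d <- fc_trip[g] - fc_dmso[g]
  wt <- wilcoxon_signed_rank(d)
  list(median_shift = median(d), p.value = wt$p.value,
       direction = if (median(d) > 0) "stabilized" else "destabilized",
       n = length(g))
}
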