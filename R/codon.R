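# Codon adaptation index with an empirically derived reference table, and
# 3'UTR extraction for motif-analysis hand-off.

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stopf("CDS length not divisible by 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Select the CAI reference genes
#'
#' The most highly expressed maternally contributed mRNA that were not
#' cleared: non-cleared maternal genes ranked by egg expression, top `top_n`.
#'
#' @param egg_tpm named vector of egg (rRNA-depleted) TPM.
#' @param stable_genes character vector of genes without clearance evidence.
#' @param top_n reference-set size (default 100).
#' @return character vector of gene ids.
#' @export
select_cai_reference <- function(egg_tpm, stable_genes, top_n = 100) {
  cand <- egg_tpm[names(egg_tpm) %in% stable_genes]
  names(sort(cand, decreasing = TRUE))[seq_len(min(top_n, length(cand)))]
}

#' Empirical codon usage table and relative adaptiveness
#'
#' Counts codon usage over the reference CDS set (61 sense codons, standard
#' code). Codons never observed receive a floor count before computing
#' relative adaptiveness `w_c = freq(c) / max freq among the codon's
#' synonyms`, so the most frequent codon of every amino acid has `w = 1` and
#' every `w` is strictly positive. Sequences with internal stops, non-ACGT
#' characters or length not divisible by 3 are skipped with a warning.
#'
#' @param cds named character vector of coding sequences (DNA, sense strand,
#'   including start and stop codons).
#' @param reference_genes genes forming the reference set (default: all of
#'   `cds`); see [select_cai_reference()].
#' @param floor count assigned to unobserved codons (default 0.5).
#' @return object of class `codon_table`: list with `counts`, `freq`, `w`
#'   (named over the 61 sense codons) and `n_genes`.
#' @export
build_codon_table <- function(cds, reference_genes = names(cds),
                              floor = 0.5) {
  sc <- sense_codons()
  use <- cds[intersect(reference_genes, names(cds))]
  counts <- setNames(numeric(length(sc)), names(sc))
  used <- 0L
  for (g in names(use)) {
    s <- toupper(use[[g]])
    if (nchar(s) %% 3 != 0 || grepl("[^ACGT]", s)) {
      warnf("skipping %s: invalid CDS", g)
      next
    }
    cod <- split_codons(s)
    internal <- cod[-length(cod)]
    if (any(!internal %in% names(sc))) {
      warnf("skipping %s: internal stop codon", g)
      next
    }
    cod <- cod[cod %in% names(sc)]
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    used <- used + 1L
  }
  if (used < 10L) stopf("fewer than 10 usable reference CDS (%d)", used)
  counts[counts == 0] <- floor
  freq <- counts / sum(counts)
  w <- counts
  for (aa in unique(sc)) {
    fam <- names(sc)[sc == aa]
    w[fam] <- counts[fam] / max(counts[fam])
  }
  structure(list(counts = counts, freq = freq, w = w, n_genes = used),
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf("codon_table from %d CDS; %d codons at w = 1\n",
              x$n_genes, sum(x$w == 1)))
  invisible(x)
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` over the codons of a CDS,
#' excluding the initiation codon, stop codons, and the single-codon amino
#' acids Met and Trp (whose `w` is 1 by construction and carries no
#' information).
#'
#' @param cds a single CDS string (start..stop) or named vector of them.
#' @param table a [build_codon_table()] result.
#' @return CAI value(s) in `(0, 1]`.
#' @export
cai <- function(cds, table) {
  stopifnot(inherits(table, "codon_table"))
  sc <- sense_codons()
  excluded <- names(sc)[sc %in% c("M", "W")]
  one <- function(s) {
    cod <- split_codons(toupper(s))[-1]           # drop initiation codon
    cod <- cod[cod %in% names(sc) & !cod %in% excluded]
    if (!length(cod)) stopf("no codons left to average")
    exp(mean(log(table$w[cod])))
  }
  if (length(cds) == 1L && is.null(names(cds))) return(one(cds))
  vapply(cds, one, numeric(1))
}

#' Extract 3'UTR sequences
#'
#' Takes transcript sequences in sense orientation plus the CDS end position
#' of each and emits the 3'UTRs longer than `min_len_exclusive` nt (a 20-nt
#' UTR is discarded, a 21-nt UTR kept). Transcripts supplied in genome
#' orientation for minus-strand genes are reverse-complemented first when a
#' strand vector is given. Genes without a known CDS end are skipped with a
#' warning.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param cds_end named integer vector: 1-based position of the last CDS base
#'   (the stop codon's final base) within each transcript.
#' @param min_len_exclusive UTRs of at most this length are discarded.
#' @param strand optional named vector (`"+"`/`"-"`).
#' @return named character vector of 3'UTRs in sense orientation.
#' @export
extract_3utrs <- function(transcripts, cds_end, min_len_exclusive = 20,
                          strand = NULL) {
  out <- character(0)
  for (g in names(transcripts)) {
    if (!g %in% names(cds_end) || is.na(cds_end[[g]])) {
      warnf("skipping %s: no CDS end annotated", g)
      next
    }
    s <- transcripts[[g]]
    if (!is.null(strand) && identical(strand[[g]], "-")) s <- revcomp(s)
    utr <- substring(s, cds_end[[g]] + 1L)
    if (nchar(utr) > min_len_exclusive) out[g] <- utr
  }
  out
}
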