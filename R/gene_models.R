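# Gene model handling: exon/intron interval structure from GTF annotations.
# GTF coordinates are 1-based inclusive; everything is converted to 0-based
# half-open internally (and BED-style output keeps that convention).

#' Build a gene model set from exon intervals
#'
#' Merged exons are the union of all transcript exons of a gene; introns are
#' the gaps between merged exons within the gene span, so introns that
#' overlap any exon are removed by construction. Single-exon genes have zero
#' intron length.
#'
#' @param exons data.frame with columns `gene_id`, `scaffold`, `strand`,
#'   `start`, `end` (1-based inclusive, GTF convention); one row per exon.
#' @return object of class `gene_models`: list with `genes` (data.frame of
#'   `gene_id`, `scaffold`, `strand`, `start0`, `end0` (0-based half-open
#'   span), `exon_bp`, `intron_bp`, `n_exons`), plus `exons` and `introns`
#'   ([GenomicRanges::GRangesList] keyed by gene).
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "scaffold", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stopf("exon table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(exons$end < exons$start)) stopf("exon end < start")
  gr <- GenomicRanges::GRanges(
    seqnames = exons$scaffold,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = exons$strand)
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, exons$gene_id))
  spans <- unlist(range(grl))
  introns <- GenomicRanges::psetdiff(spans, grl)
  genes <- data.frame(
    gene_id = names(grl),
    scaffold = as.character(GenomicRanges::seqnames(spans)),
    strand = as.character(GenomicRanges::strand(spans)),
    start0 = GenomicRanges::start(spans) - 1L,
    end0 = GenomicRanges::end(spans),
    exon_bp = sum(GenomicRanges::width(grl)),
    intron_bp = sum(GenomicRanges::width(introns)),
    n_exons = lengths(grl),
    row.names = NULL)
  structure(list(genes = genes, exons = grl, introns = introns),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d scaffolds (%d intronless)\n",
              nrow(x$genes), length(unique(x$genes$scaffold)),
              sum(x$genes$intron_bp == 0)))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' @param path GTF file; `exon` features with `gene_id` attributes are used.
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stopf("no exon features in %s", path)
  gene_models(data.frame(
    gene_id = gr$gene_id,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)))
}

#' Write exon intervals as GTF
#'
#' @param exons exon data.frame as accepted by [gene_models()], with an
#'   optional `transcript_id` column.
#' @param path output path.
#' @export
write_gtf <- function(exons, path) {
  tx <- exons$transcript_id %||% paste0(exons$gene_id, ".t1")
  lines <- sprintf(
    "%s\tmztseq\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$scaffold, exons$start, exons$end, exons$strand,
    exons$gene_id, tx)
  writeLines(lines, path)
  invisible(path)
}

#' Effective gene lengths for TPM
#'
#' Summed merged-exon length per gene (the union-exon convention).
#'
#' @param models a [gene_models()] object.
#' @return named numeric vector of lengths in bp.
#' @export
gene_lengths <- function(models) {
  setNames(models$genes$exon_bp, models$genes$gene_id)
}
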