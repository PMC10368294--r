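# Sequence-level forward simulation: coding sequences with controllable codon
# bias, 3'UTRs carrying implanted miRNA hairpins / target sites / decoys, and
# the reference mature miRNA set used by the homology scan.

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

#' Codon usage tables of the simulated bias groups
#'
#' `high_bias`: within every synonymous family one codon carries 85% of the
#' usage; `low_bias`: uniform within families. Used by the generator to
#' realize codon-bias groups and by tests as the known sampling truth.
#'
#' @param group `"high_bias"` or `"low_bias"`.
#' @return named numeric vector over the 61 sense codons, summing to 1 within
#'   each synonymous family.
#' @export
sim_codon_usage <- function(group = c("high_bias", "low_bias")) {
  group <- match.arg(group)
  sc <- sense_codons()
  out <- numeric(length(sc))
  names(out) <- names(sc)
  for (aa in unique(sc)) {
    fam <- sort(names(sc)[sc == aa])
    if (group == "low_bias" || length(fam) == 1L) {
      out[fam] <- 1 / length(fam)
    } else {
      out[fam] <- 0.15 / (length(fam) - 1)
      out[fam[1]] <- 0.85
    }
  }
  out
}

random_cds <- function(n_codons, usage) {
  sc <- sense_codons()
  aas <- setdiff(unique(sc), c("M", "W"))   # single-codon families add no bias
  aa_seq <- sample(aas, n_codons, replace = TRUE)
  cod <- vapply(aa_seq, function(a) {
    fam <- names(sc)[sc == a]
    sample(fam, 1, prob = usage[fam])
  }, character(1))
  paste0("ATG", paste(cod, collapse = ""), "TAA")
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# mRNA base that pairs with miRNA base q (miRNA given in DNA spelling)
wc_partner <- function(q) DNA_COMP[q]
gu_partner <- function(q) c(G = "T", T = "G")[q]          # G:U wobble
mismatch_partner <- function(q) {
  opts <- list(A = c("A", "C", "G"), C = c("A", "C", "T"),
               G = c("A", "G"), T = c("C", "T"))[[q]]
  sample(opts, 1)
}

# build a target site on the mRNA sense strand for `mature` (DNA spelling):
# reverse complement with gu G:U conversions and mm mismatches implanted
make_site <- function(mature, gu = 0, mm = 0) {
  q <- strsplit(mature, "")[[1]]
  L <- length(q)
  m <- unname(wc_partner(q))
  kind <- rep("wc", L)
  elig_gu <- which(q %in% c("G", "T"))
  if (gu > length(elig_gu)) stopf("not enough G/U positions for wobble sites")
  pos_gu <- if (gu > 0) sample(elig_gu, gu) else integer(0)
  pos_mm <- if (mm > 0) sample(setdiff(seq_len(L), pos_gu), mm) else integer(0)
  for (i in pos_gu) { m[i] <- gu_partner(q[i]); kind[i] <- "gu" }
  for (i in pos_mm) { m[i] <- mismatch_partner(q[i]); kind[i] <- "mm" }
  list(site = paste(rev(m), collapse = ""), wc = sum(kind == "wc"),
       gu = gu, mm = mm)
}

mutate_seq <- function(seq, k) {
  if (k == 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(s), k)
  for (i in pos) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  paste(s, collapse = "")
}

random_dna <- function(n, prob = c(A = .3, C = .2, G = .2, T = .3)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

# mature miRNAs are sequence-complex: balanced composition, no long runs
# (a near-homopolymer mature would pair half the transcriptome once G:U
# wobble is allowed, which no curated miRNA set resembles)
random_mature <- function(n, max_frac = 0.4, max_run = 5) {
  repeat {
    s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    runs <- rle(s)$lengths
    if (max(table(s)) <= max_frac * n && max(runs) <= max_run)
      return(paste(s, collapse = ""))
  }
}

#' Simulate transcript, CDS, 3'UTR and reference miRNA sequences
#'
#' Coding sequences are sampled codon-by-codon from the usage table of each
#' gene's codon-bias group. Each pri-miRNA host transcript carries a perfect
#' stem-loop in its 3'UTR whose designated arm equals the mature miRNA; each
#' miRNA-target 3'UTR carries the reverse complement of its partner mature
#' sequence with the configured number of G:U conversions and mismatches;
#' decoy sites in stable maternal 3'UTRs carry `decoy_mismatch` mismatches.
#' The reference mature-miRNA set differs from the implanted matures by
#' `ref_mismatch` substitutions (recycled over miRNAs), emulating homologs
#' from a sister species.
#'
#' @param truth a [simulate_truth()] result.
#' @param config matching [simulation_config()].
#' @return list with named character vectors `cds`, `utr3`, `transcripts`
#'   (DNA, sense orientation), `mirna_refs` (RNA spelling), plus data.frames
#'   `mirna_truth` (mature sequence, host, arm, 1-based transcript
#'   coordinates of mature and hairpin) and `target_truth` (gene, partner,
#'   site coordinates, implanted WC/G:U/mismatch tallies, `decoy` flag).
#' @export
simulate_sequences <- function(truth, config = truth$config) {
  cfg <- config
  if (cfg$mirna_len < 18 || cfg$mirna_len > 25)
    stopf("mature miRNA length must lie in [18, 25] nt")
  g <- truth$genes
  with_stream(cfg$seed, 4, {
    usage <- list(high_bias = sim_codon_usage("high_bias"),
                  low_bias = sim_codon_usage("low_bias"))
    n <- nrow(g)
    cds <- character(n)
    for (i in seq_len(n))
      cds[i] <- random_cds(g$cds_len[i] / 3 - 2, usage[[g$codon_group[i]]])
    names(cds) <- g$gene_id

    hosts <- which(g$is_mirna_host)
    matures <- setNames(vapply(seq_along(hosts),
                               function(i) random_mature(cfg$mirna_len),
                               character(1)),
                        g$mirna_id[hosts])
    arms <- rep_len(c("5p", "3p"), length(hosts))

    utr3 <- character(n)
    mir_rows <- list()
    tgt_rows <- list()
    for (i in seq_len(n)) {
      u <- random_dna(g$utr3_len[i])
      utr_off <- 50L + g$cds_len[i]   # transcript position before the UTR
      if (g$is_mirna_host[i]) {
        k <- match(i, hosts)
        mat <- matures[[g$mirna_id[i]]]
        star <- revcomp(mat)
        hp <- if (arms[k] == "5p")
          paste0(mat, random_dna(cfg$hairpin_loop_len), star)
        else paste0(star, random_dna(cfg$hairpin_loop_len), mat)
        at <- 21L   # hairpin begins at UTR position 21
        substr(u, at, at + nchar(hp) - 1L) <- hp
        mat_at <- if (arms[k] == "5p") at
                  else at + cfg$mirna_len + cfg$hairpin_loop_len
        mir_rows[[length(mir_rows) + 1L]] <- data.frame(
          mirna_id = g$mirna_id[i], host_gene = g$gene_id[i],
          mature = chartr("T", "U", mat), arm = arms[k],
          mature_start = utr_off + mat_at,
          mature_end = utr_off + mat_at + cfg$mirna_len - 1L,
          hairpin_start = utr_off + at,
          hairpin_end = utr_off + at + nchar(hp) - 1L)
      }
      if ((g$is_mirna_target[i] || g$is_decoy[i]) &&
          !is.na(g$partner_mirna[i]) &&
          g$partner_mirna[i] %in% names(matures)) {
        mat <- matures[[g$partner_mirna[i]]]
        site <- if (g$is_decoy[i])
          make_site(mat, gu = 0, mm = cfg$decoy_mismatch)
        else make_site(mat, gu = cfg$target_site_gu,
                       mm = cfg$target_site_mismatch)
        at <- 21L
        substr(u, at, at + nchar(site$site) - 1L) <- site$site
        tgt_rows[[length(tgt_rows) + 1L]] <- data.frame(
          gene_id = g$gene_id[i], mirna_id = g$partner_mirna[i],
          site_start = utr_off + at,
          site_end = utr_off + at + cfg$mirna_len - 1L,
          wc = site$wc, gu = site$gu, mm = site$mm, decoy = g$is_decoy[i])
      }
      utr3[i] <- u
    }
    names(utr3) <- g$gene_id
    utr5 <- vapply(seq_len(n), function(i) random_dna(50L), character(1))
    transcripts <- setNames(paste0(utr5, cds, utr3), g$gene_id)

    ref_mm <- rep_len(cfg$ref_mismatch, length(hosts))
    refs <- setNames(vapply(seq_along(hosts), function(k)
      chartr("T", "U", mutate_seq(matures[[k]], ref_mm[k])), character(1)),
      paste0("ref-", names(matures)))

    list(cds = cds, utr3 = utr3, transcripts = transcripts,
         mirna_refs = refs,
         mirna_truth = if (length(mir_rows)) do.call(rbind, mir_rows)
                       else NULL,
         target_truth = if (length(tgt_rows)) do.call(rbind, tgt_rows)
                        else NULL,
         ref_mismatch = setNames(ref_mm, names(matures)))
  })
}
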