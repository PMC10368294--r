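# miRNA candidate discovery and full-complementarity target prediction.
# Folding uses a Nussinov maximum base-pairing dynamic program (self-
# contained and brute-force verifiable) rather than a thermodynamic model;
# stem/loop geometry, not free energy, is the operative criterion here.

norm_rna <- function(x) chartr("tu", "TU", chartr("T", "U", toupper(x)))

pair_ok_matrix <- function(allow_gu) {
  base <- c("A", "C", "G", "U", "N")
  m <- matrix(FALSE, 5, 5, dimnames = list(base, base))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- TRUE
  if (allow_gu) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

#' Maximum base-pairing RNA fold (Nussinov)
#'
#' Computes a pseudoknot-free secondary structure maximizing the number of
#' base pairs over `{AU, UA, GC, CG}` plus `{GU, UG}` when `allow_gu`, with a
#' minimal hairpin loop of `min_loop` unpaired bases. The traceback is
#' deterministic: whenever pairing achieves the optimum, the opening base is
#' paired with the smallest admissible partner. `N` never pairs; other
#' non-ACGU characters are an error. Intended for short windows (the
#' candidate hairpin scale), not whole transcripts.
#'
#' @param seq RNA or DNA string (T is read as U), length <= 500.
#' @param allow_gu allow G:U wobble pairs (default TRUE).
#' @param min_loop minimal loop length (default 3).
#' @return list with `structure` (dot-bracket), `pairs` (partner index per
#'   position, `NA` if unpaired) and `n_pairs`.
#' @export
fold_hairpin <- function(seq, allow_gu = TRUE, min_loop = 3) {
  s <- strsplit(norm_rna(seq), "")[[1]]
  bad <- setdiff(unique(s), c("A", "C", "G", "U", "N"))
  if (length(bad)) stopf("invalid characters in sequence: %s",
                         paste(bad, collapse = ""))
  n <- length(s)
  if (n > 500) stopf("sequence too long for the folding DP (%d nt)", n)
  pm <- pair_ok_matrix(allow_gu)
  if (n < min_loop + 2) {
    return(list(structure = paste(rep(".", n), collapse = ""),
                pairs = rep(NA_integer_, n), n_pairs = 0L))
  }
  can <- pm[s, s, drop = FALSE]
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i + 1, j]
      ks <- (i + min_loop + 1):j
      ks <- ks[can[i, ks]]
      if (length(ks)) {
        inner <- ifelse(ks - 1 >= i + 1, N[cbind(i + 1, pmax(ks - 1, i + 1))],
                        0L)
        inner[ks - 1 < i + 1] <- 0L
        right <- ifelse(ks + 1 <= j, N[cbind(pmin(ks + 1, j), j)], 0L)
        right[ks + 1 > j] <- 0L
        best <- max(best, max(1L + inner + right))
      }
      N[i, j] <- best
    }
  }
  pairs <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (i < j && j - i > min_loop) {
      target <- N[i, j]
      if (target == 0L) break
      ks <- (i + min_loop + 1):j
      ks <- ks[can[i, ks]]
      found <- FALSE
      for (k in ks) {
        inner <- if (k - 1 >= i + 1) N[i + 1, k - 1] else 0L
        right <- if (k + 1 <= j) N[k + 1, j] else 0L
        if (1L + inner + right == target) {
          pairs[i] <- k
          pairs[k] <- i
          if (k + 1 <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          found <- TRUE
          break
        }
      }
      if (!found) i <- i + 1L    # i unpaired
    }
  }
  db <- rep(".", n)
  db[!is.na(pairs) & seq_len(n) < pairs] <- "("
  db[!is.na(pairs) & seq_len(n) > pairs] <- ")"
  list(structure = paste(db, collapse = ""), pairs = pairs,
       n_pairs = sum(!is.na(pairs)) / 2L)
}

count_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Ungapped homology scan of reference miRNAs against transcripts
#'
#' Seed-and-extend scan emulating an ungapped word search: every exact
#' `word_size`-mer of a reference seeds a full-length ungapped alignment on
#' both strands, and alignments with at most `max_mismatch` mismatches are
#' reported. Overlapping hits of the same reference on the same transcript
#' and strand are deduplicated keeping the fewest-mismatch (then leftmost)
#' hit.
#'
#' @param refs named character vector of mature reference miRNAs (18-25 nt,
#'   RNA or DNA spelling).
#' @param transcripts named character vector of transcript sequences (DNA,
#'   sense orientation).
#' @param word_size exact seed length (default 7).
#' @param max_mismatch maximal mismatches over the full reference length
#'   (default 2).
#' @return data.frame `ref_id`, `transcript_id`, `start`, `end` (1-based on
#'   the transcript), `strand`, `mismatches`, `mature` (the transcript-sense
#'   sequence that, read on `strand`, matches the reference).
#' @export
scan_reference_mirnas <- function(refs, transcripts, word_size = 7,
                                  max_mismatch = 2) {
  if (any(nchar(refs) < word_size))
    stopf("reference shorter than word_size")
  if (any(nchar(refs) < 18 | nchar(refs) > 25))
    stopf("reference mature miRNAs must be 18-25 nt")
  txset <- Biostrings::DNAStringSet(chartr("Uu", "Tt", transcripts))
  hits <- list()
  for (rid in names(refs)) {
    qdna <- chartr("U", "T", norm_rna(refs[[rid]]))
    L <- nchar(qdna)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") qdna else revcomp(qdna)
      seeds <- unique(substring(pat, seq_len(L - word_size + 1),
                                word_size:L))
      cand <- list()
      for (si in seq_along(seeds)) {
        mt <- Biostrings::vmatchPattern(seeds[si], txset)
        offs <- seq_len(L - word_size + 1)[
          substring(pat, seq_len(L - word_size + 1), word_size:L) ==
            seeds[si]]
        for (ti in which(lengths(mt) > 0)) {
          p <- Biostrings::startIndex(mt)[[ti]]
          st <- unique(as.vector(outer(p, offs - 1L, `-`)))
          st <- st[st >= 1 & st + L - 1 <= nchar(transcripts[ti])]
          if (length(st))
            cand[[length(cand) + 1L]] <- data.frame(ti = ti, start = st)
        }
      }
      if (!length(cand)) next
      cd <- unique(do.call(rbind, cand))
      for (r in seq_len(nrow(cd))) {
        ti <- cd$ti[r]
        st <- cd$start[r]
        sub <- substring(transcripts[[ti]], st, st + L - 1)
        # for '-' hits pat is already the reverse complement of the reference
        mm <- count_mismatches(sub, pat)
        if (mm <= max_mismatch)
          hits[[length(hits) + 1L]] <- data.frame(
            ref_id = rid, transcript_id = names(transcripts)[ti],
            start = st, end = st + L - 1, strand = strand,
            mismatches = mm,
            mature = if (strand == "+") sub else revcomp(sub))
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(ref_id = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0), mature = character(0))
  dedup_hits(out)
}

# keep, per (ref, transcript, strand), the best hit among overlapping ones
dedup_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$ref_id, hits$transcript_id, hits$strand,
                     hits$mismatches, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  taken <- list()
  for (r in seq_len(nrow(hits))) {
    key <- paste(hits$ref_id[r], hits$transcript_id[r], hits$strand[r])
    iv <- taken[[key]]
    ov <- !is.null(iv) &&
      any(hits$start[r] <= iv[, 2] & hits$end[r] >= iv[, 1])
    if (!ov) {
      keep[r] <- TRUE
      taken[[key]] <- rbind(iv, c(hits$start[r], hits$end[r]))
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate the stem-loop context of a homology hit
#'
#' Folds the hit plus flanking sequence with [fold_hairpin()] and asks
#' whether the putative mature sequence sits on one arm of a hairpin: at
#' least `stem_min` mature positions must pair with partners outside the
#' mature region, with a consistent direction that assigns the arm (5p:
#' partners downstream; 3p: upstream). The deviation of the observed pairing
#' register from a blunt-ended duplex is recorded (`register_offset`, a
#' heuristic annotation of non-canonical Drosha/Dicer geometry) but never
#' used to reject a candidate.
#'
#' @param hit one row of a [scan_reference_mirnas()] result.
#' @param transcripts named character vector of transcripts.
#' @param flank nt of context folded on each side (default 60).
#' @param stem_min minimal mature positions paired into the stem (default 14).
#' @param min_loop,allow_gu folding parameters.
#' @return one-row data.frame: hit columns plus `arm`, `stem_pairs`,
#'   `loop_len`, `register_offset`, `truncated`, `pass`, `structure`.
#' @export
detect_stem_loop <- function(hit, transcripts, flank = 60, stem_min = 14,
                             min_loop = 3, allow_gu = TRUE) {
  tx <- transcripts[[hit$transcript_id]]
  n <- nchar(tx)
  ws <- max(1L, hit$start - flank)
  we <- min(n, hit$end + flank)
  truncated <- (hit$start - flank < 1) || (hit$end + flank > n)
  win <- substring(tx, ws, we)
  fold <- fold_hairpin(win, allow_gu = allow_gu, min_loop = min_loop)
  ms <- hit$start - ws + 1L
  me <- hit$end - ws + 1L
  idx <- ms:me
  partner <- fold$pairs[idx]
  stem <- !is.na(partner) & (partner < ms | partner > me)
  up <- sum(stem & partner < ms)
  down <- sum(stem & partner > me)
  arm <- if (down > up) "5p" else if (up > down) "3p" else NA_character_
  stem_pairs <- max(up, down)
  loop_len <- NA_integer_
  reg <- NA_integer_
  if (any(stem)) {
    i_in <- idx[stem]
    p_in <- partner[stem]
    span <- abs(p_in - i_in)
    loop_len <- min(span) - 1L
    outer_pair <- which(!is.na(fold$pairs) & seq_along(fold$pairs) <
                          fold$pairs)
    if (length(outer_pair)) {
      omin <- min(outer_pair)
      reg <- as.integer(round(median(i_in + p_in)) -
                          (omin + fold$pairs[omin]))
    }
  }
  cbind(hit, data.frame(
    arm = arm, stem_pairs = stem_pairs, loop_len = loop_len,
    register_offset = reg, truncated = truncated,
    pass = !is.na(arm) && stem_pairs >= stem_min &&
      (is.na(loop_len) || loop_len >= min_loop),
    structure = fold$structure))
}

#' Assemble miRNA hairpin candidates from a homology scan
#'
#' Runs [detect_stem_loop()] on every hit.
#'
#' @param hits a [scan_reference_mirnas()] result.
#' @inheritParams detect_stem_loop
#' @return data.frame of evaluated candidates (one row per hit).
#' @export
mirna_candidates <- function(hits, transcripts, flank = 60, stem_min = 14,
                             min_loop = 3, allow_gu = TRUE) {
  if (!nrow(hits)) return(hits)
  out <- do.call(rbind, lapply(seq_len(nrow(hits)), function(r)
    detect_stem_loop(hits[r, , drop = FALSE], transcripts, flank = flank,
                     stem_min = stem_min, min_loop = min_loop,
                     allow_gu = allow_gu)))
  rownames(out) <- NULL
  out
}

#' Filter hairpin candidates by zygotic activation
#'
#' Retains structural candidates whose source transcript is significantly
#' activated (adjusted p < `padj_max`, positive fold) and annotates
#' transcription dependence: `triptolide_inhibited` is `TRUE` when the
#' transcript is significantly down in triptolide vs DMSO. The annotation is
#' reported, not required - a small maternal contribution is tolerated.
#'
#' @param candidates a [mirna_candidates()] result (rows with `pass` are
#'   retained).
#' @param activation_de a [nb_test()] result (or list of them over
#'   timepoints) for the transcripts, contrast later-vs-egg.
#' @param trip_de optional [nb_test()] result, triptolide vs DMSO.
#' @param padj_max significance threshold (default 0.05).
#' @return filtered data.frame with `activation_padj`,
#'   `triptolide_inhibited` columns.
#' @export
filter_candidates <- function(candidates, activation_de, trip_de = NULL,
                              padj_max = 0.05) {
  if (!nrow(candidates)) return(candidates)
  delist <- if (inherits(activation_de, "data.frame")) list(activation_de)
            else activation_de
  best <- rep(NA_real_, nrow(candidates))
  for (de in delist) {
    i <- match(candidates$transcript_id, de$gene_id)
    p <- ifelse(!is.na(i) & !de$filtered[i] & de$log2FoldChange[i] > 0,
                de$padj[i], NA_real_)
    best <- pmin(best, p, na.rm = TRUE)
  }
  keep <- candidates$pass & !is.na(best) & best < padj_max
  out <- candidates[keep, , drop = FALSE]
  out$activation_padj <- best[keep]
  out$triptolide_inhibited <- FALSE
  if (!is.null(trip_de) && nrow(out)) {
    i <- match(out$transcript_id, trip_de$gene_id)
    out$triptolide_inhibited <- !is.na(i) & !is.na(trip_de$padj[i]) &
      trip_de$padj[i] < padj_max & trip_de$log2FoldChange[i] < 0
  }
  rownames(out) <- NULL
  out
}

# per-position duplex classification of miRNA q (5'->3') against an mRNA
# site m (sense): position i of q faces base L+1-i of m
classify_duplex <- function(mature_dna, site) {
  q <- strsplit(mature_dna, "")[[1]]
  m <- rev(strsplit(site, "")[[1]])
  wc <- unname(DNA_COMP[q]) == m
  gu <- (q == "G" & m == "T") | (q == "T" & m == "G")
  kind <- ifelse(wc, "|", ifelse(gu, ":", "."))
  list(wc = sum(wc), gu = sum(gu & !wc), mm = sum(!wc & !gu),
       pairing = paste(kind, collapse = ""))
}

#' Predict fully complementary miRNA targets
#'
#' Ungapped antisense scan: every exact `word_size`-mer of the reverse
#' complement of a mature miRNA seeds a full-length anchored alignment on the
#' mRNA; at each anchor every miRNA position is classified as Watson-Crick,
#' G:U wobble, or mismatch, and duplexes with a paired fraction
#' (`(WC + GU) / length`) of at least `min_paired_fraction` are reported.
#' Hits in the stable-mRNA control set are reported with `set = "control"`
#' as a specificity readout.
#'
#' @param matures named character vector of mature miRNA sequences (the
#'   candidates), RNA or DNA spelling.
#' @param target_seqs named character vector of cleared-mRNA sequences
#'   (sense).
#' @param control_seqs optional stable-mRNA control sequences.
#' @param word_size exact antisense seed length (default 4).
#' @param min_paired_fraction duplex acceptance threshold (default 0.85).
#' @return data.frame `mirna_id`, `gene_id`, `set`, `start`, `end`, `wc`,
#'   `gu`, `mismatch`, `paired_fraction`, `pairing` (`|` WC, `:` G:U, `.`
#'   mismatch, 5'->3' of the miRNA).
#' @export
predict_targets <- function(matures, target_seqs, control_seqs = NULL,
                            word_size = 4, min_paired_fraction = 0.85) {
  if (!length(matures))
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      set = character(0), start = integer(0),
                      end = integer(0), wc = integer(0), gu = integer(0),
                      mismatch = integer(0), paired_fraction = numeric(0),
                      pairing = character(0)))
  sets <- list(target = target_seqs)
  if (!is.null(control_seqs)) sets$control <- control_seqs
  rows <- list()
  for (mid in names(matures)) {
    qdna <- chartr("U", "T", norm_rna(matures[[mid]]))
    L <- nchar(qdna)
    rcq <- revcomp(qdna)
    offs_all <- seq_len(L - word_size + 1)
    seeds <- substring(rcq, offs_all, offs_all + word_size - 1)
    useeds <- unique(seeds)
    for (sname in names(sets)) {
      seqs <- sets[[sname]]
      if (!length(seqs)) next
      sset <- Biostrings::DNAStringSet(chartr("Uu", "Tt", seqs))
      cand <- list()
      for (sd in useeds) {
        mt <- Biostrings::vmatchPattern(sd, sset)
        offs <- offs_all[seeds == sd]
        hit_ti <- which(lengths(mt) > 0)
        if (!length(hit_ti)) next
        si <- Biostrings::startIndex(mt)[hit_ti]
        ti_rep <- rep(hit_ti, lengths(si))
        p <- unlist(si, use.names = FALSE)
        st <- rep(p, each = length(offs)) - rep(offs - 1L, length(p))
        ti2 <- rep(ti_rep, each = length(offs))
        ok <- st >= 1 & st + L - 1 <= nchar(seqs)[ti2]
        if (any(ok))
          cand[[length(cand) + 1L]] <- cbind(ti = ti2[ok], start = st[ok])
      }
      if (!length(cand)) next
      cd <- unique(do.call(rbind, cand))
      cd <- as.data.frame(cd)
      sites <- substring(seqs[cd$ti], cd$start, cd$start + L - 1)
      # batch per-position classification: site column i faces miRNA base
      # L + 1 - i, so compare against the reversed pairing targets
      sm <- matrix(unlist(strsplit(sites, "", fixed = TRUE)), nrow = L)
      qv <- strsplit(qdna, "")[[1]]
      wc_t <- rev(unname(DNA_COMP[qv]))
      gu_t <- rev(unname(c(G = "T", T = "G")[qv]))
      is_wc <- sm == wc_t
      is_gu <- !is_wc & sm == gu_t & !is.na(gu_t)
      wc_n <- colSums(is_wc)
      gu_n <- colSums(is_gu)
      pf <- (wc_n + gu_n) / L
      ok <- which(pf >= min_paired_fraction)
      for (r in ok) {
        kind <- rev(ifelse(is_wc[, r], "|", ifelse(is_gu[, r], ":", ".")))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, gene_id = names(seqs)[cd$ti[r]], set = sname,
          start = cd$start[r], end = cd$start[r] + L - 1, wc = wc_n[r],
          gu = gu_n[r], mismatch = L - wc_n[r] - gu_n[r],
          paired_fraction = pf[r], pairing = paste(kind, collapse = ""))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               set = character(0), start = integer(0), end = integer(0),
               wc = integer(0), gu = integer(0), mismatch = integer(0),
               paired_fraction = numeric(0), pairing = character(0))
  # best non-overlapping duplex per miRNA/gene
  if (nrow(out)) {
    out <- out[order(out$mirna_id, out$gene_id, -out$paired_fraction,
                     out$mismatch, out$start), , drop = FALSE]
    keep <- logical(nrow(out))
    taken <- list()
    for (r in seq_len(nrow(out))) {
      key <- paste(out$mirna_id[r], out$gene_id[r], out$set[r])
      iv <- taken[[key]]
      ov <- !is.null(iv) && any(out$start[r] <= iv[, 2] &
                                  out$end[r] >= iv[, 1])
      if (!ov) {
        keep[r] <- TRUE
        taken[[key]] <- rbind(iv, c(out$start[r], out$end[r]))
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
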