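# Folding, homology scan, stem-loop evaluation, target prediction.

test_that("Nussinov folding reproduces hand-checkable structures", {
  f <- fold_hairpin("GGGAAACCC")
  expect_equal(f$n_pairs, 3)
  expect_identical(f$structure, "(((...)))")

  expect_equal(fold_hairpin("AAAAAAA")$n_pairs, 0)

  expect_equal(fold_hairpin("GGGAAAUUU", allow_gu = TRUE)$n_pairs, 3)
  # without wobble only a single nested A:U pair fits the min-loop rule
  expect_equal(fold_hairpin("GGGAAAUUU", allow_gu = FALSE)$n_pairs,
               brute_max_pairs("GGGAAAUUU", allow_gu = FALSE))
  expect_equal(fold_hairpin("GGGAAAUUU", allow_gu = FALSE)$n_pairs, 1)

  expect_error(fold_hairpin("ACGX"), "invalid characters")
  # N never pairs
  expect_equal(fold_hairpin("NNNAAANNN")$n_pairs, 0)
  # DNA spelling accepted
  expect_equal(fold_hairpin("GGGAAACCC")$n_pairs,
               fold_hairpin("gggaaaccc")$n_pairs)
})

test_that("folding equals exhaustive maximum pairing up to length 12", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    gu <- rep %% 2 == 0
    expect_equal(fold_hairpin(s, allow_gu = gu)$n_pairs,
                 brute_max_pairs(s, allow_gu = gu),
                 info = sprintf("seq=%s gu=%s", s, gu))
  }
})

test_that("structures from the traceback are valid and deterministic", {
  set.seed(24)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE),
               collapse = "")
    f1 <- fold_hairpin(s)
    f2 <- fold_hairpin(s)
    expect_identical(f1$structure, f2$structure)
    p <- f1$pairs
    idx <- which(!is.na(p))
    # symmetric partners, min loop respected, pair count consistent
    expect_true(all(p[p[idx]] == idx))
    expect_true(all(abs(p[idx] - idx) > 3))
    expect_equal(sum(!is.na(p)) / 2, f1$n_pairs)
  }
})

test_that("the homology scan seeds, extends, and deduplicates", {
  set.seed(25)
  mat <- "ACGTGGTCAACGTTAGGCTAAC"   # 22 nt
  tx1 <- paste0(strrep("A", 50), mat, strrep("C", 50))
  mat3 <- mat
  substr(mat3, 3, 5) <- "TAC"       # 3 mismatches vs mat
  tx2 <- paste0(strrep("G", 30), mat3, strrep("A", 40))
  tx3 <- paste0(strrep("T", 40), mztseq:::revcomp(mat), strrep("G", 30))
  txs <- c(t1 = tx1, t2 = tx2, t3 = tx3)
  refs <- c(r1 = chartr("T", "U", mat))
  hits <- scan_reference_mirnas(refs, txs)
  expect_setequal(hits$transcript_id, c("t1", "t3"))
  h1 <- hits[hits$transcript_id == "t1", ]
  expect_equal(h1$start, 51)
  expect_equal(h1$mismatches, 0)
  expect_identical(h1$strand, "+")
  h3 <- hits[hits$transcript_id == "t3", ]
  expect_identical(h3$strand, "-")
  expect_equal(h3$start, 41)
  expect_identical(h3$mature, mat)   # reverse-complemented back to the ref

  # 3 mismatches exceeds the default ceiling, 3 allowed finds it
  hits3 <- scan_reference_mirnas(refs, txs, max_mismatch = 3)
  expect_true("t2" %in% hits3$transcript_id)

  expect_error(scan_reference_mirnas(c(r = "ACGUAC"), txs),
               "18-25|word_size")
})

test_that("stem-loop evaluation assigns arms and rejects loop matures", {
  set.seed(26)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  mat <- "ACGTGGTCAACGTTAGGCTAAC"
  loop <- rnd(8)
  hp5 <- paste0(mat, loop, mztseq:::revcomp(mat))
  tx <- paste0(rnd(30), hp5, rnd(30))
  hit <- data.frame(ref_id = "r", transcript_id = "t", start = 31,
                    end = 31 + 21, strand = "+", mismatches = 0,
                    mature = mat)
  res <- detect_stem_loop(hit, c(t = tx))
  expect_true(res$pass)
  expect_identical(res$arm, "5p")
  expect_gte(res$stem_pairs, 14)

  hit3 <- hit
  hit3$start <- 31 + 22 + 8
  hit3$end <- hit3$start + 21
  res3 <- detect_stem_loop(hit3, c(t = tx))
  expect_identical(res3$arm, "3p")
  expect_true(res3$pass)

  # mature buried in a loop between two unrelated stems fails stem_min
  stemA <- "GCATGCTTGCAGCA"
  lonely <- paste0(stemA, strrep("A", 4), mztseq:::revcomp(stemA),
                   mat,   # unpaired island
                   rnd(8))
  hitL <- data.frame(ref_id = "r", transcript_id = "t", start = 33,
                     end = 33 + 21, strand = "+", mismatches = 0,
                     mature = mat)
  resL <- detect_stem_loop(hitL, c(t = lonely), flank = 40)
  expect_false(resL$pass)
  expect_true(resL$truncated)
})

test_that("candidate filtering requires activation and annotates triptolide", {
  cand <- data.frame(ref_id = "r", transcript_id = c("act", "flat", "weak"),
                     start = 1, end = 22, strand = "+", mismatches = 0,
                     mature = "ACGTGGTCAACGTTAGGCTAAC", arm = "5p",
                     stem_pairs = 20, loop_len = 8, register_offset = 0,
                     truncated = FALSE, pass = TRUE, structure = ".")
  act_de <- data.frame(gene_id = c("act", "flat", "weak"), baseMean = 10,
                       log2FoldChange = c(5, 0.1, 4),
                       pvalue = c(1e-9, 0.9, 0.1),
                       padj = c(1e-8, 0.95, 0.2), filtered = FALSE)
  trip_de <- data.frame(gene_id = c("act", "flat", "weak"), baseMean = 10,
                        log2FoldChange = c(-4, 0, 0),
                        pvalue = c(1e-6, 1, 1),
                        padj = c(1e-5, 1, 1), filtered = FALSE)
  kept <- filter_candidates(cand, act_de, trip_de)
  expect_identical(kept$transcript_id, "act")       # padj 0.2 is dropped
  expect_true(kept$triptolide_inhibited)
})

test_that("target duplexes classify WC, G:U and mismatches exactly", {
  mat <- "ACGTGGTCAACGTTAGGCTAAC"
  site_exact <- mztseq:::revcomp(mat)
  # convert one WC pair to G:U: mature G pairs site T
  qv <- strsplit(mat, "")[[1]]
  gpos <- which(qv == "G")[1]
  site_gu <- strsplit(site_exact, "")[[1]]
  site_gu[23 - gpos] <- "T"
  site_gu <- paste(site_gu, collapse = "")
  # four mismatches -> paired fraction 18/22 < 0.85
  site_mm <- strsplit(site_exact, "")[[1]]
  for (i in which(qv %in% c("A"))[1:4]) site_mm[23 - i] <- "C"
  site_mm <- paste(site_mm, collapse = "")
  mk <- function(site) paste0(strrep("G", 25), site, strrep("A", 25))
  targets <- c(exact = mk(site_exact), wobble = mk(site_gu),
               reject = mk(site_mm))
  res <- predict_targets(c(m1 = mat), targets)
  expect_setequal(res$gene_id, c("exact", "wobble"))
  ex <- res[res$gene_id == "exact", ]
  expect_equal(ex$paired_fraction, 1)
  expect_equal(ex$gu, 0)
  expect_equal(ex$wc, 22)
  expect_identical(ex$pairing, strrep("|", 22))
  expect_equal(ex$start, 26)
  wb <- res[res$gene_id == "wobble", ]
  expect_equal(wb$paired_fraction, 1)
  expect_equal(wb$gu, 1)
  expect_equal(wb$mismatch, 0)
  expect_equal(substr(wb$pairing, gpos, gpos), ":")

  # control sequences are reported under their own set label
  res2 <- predict_targets(c(m1 = mat), targets["exact"],
                          control_seqs = targets["wobble"])
  expect_setequal(res2$set, c("target", "control"))

  expect_equal(nrow(predict_targets(character(0), targets)), 0)
})
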