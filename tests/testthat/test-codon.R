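# Codon usage table, CAI, and 3'UTR extraction.

test_that("relative adaptiveness follows observed synonymous frequencies", {
  # 75/25 split between two Asn codons (AAT/AAC), everything else unseen
  cds <- setNames(rep(paste0("ATG", strrep("AAT", 75), strrep("AAC", 25),
                             strrep("GGA", 40), "TAA"), 12),
                  sprintf("g%d", 1:12))
  tab <- build_codon_table(cds, floor = 0.5)
  expect_equal(unname(tab$w["AAT"]), 1)
  expect_equal(unname(tab$w["AAC"]), 25 / 75)
  # an unseen codon whose synonym was observed gets the floor-derived w
  expect_equal(unname(tab$w["GGG"]), 0.5 / (40 * 12))
  # a fully unobserved family is uninformative: every member at w = 1
  expect_true(all(tab$w[c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")] == 1))
  expect_true(all(tab$w > 0 & tab$w <= 1))
  # one w = 1 per amino-acid family
  sc <- mztseq:::sense_codons()
  for (aa in unique(sc))
    expect_equal(max(tab$w[names(sc)[sc == aa]]), 1)
})

test_that("codon table recovers known sampling frequencies", {
  cfg <- simulation_config(n_genes = 150, seed = 17)
  truth <- simulate_truth(cfg)
  seqs <- simulate_sequences(truth, cfg)
  hi <- truth$genes$gene_id[truth$genes$codon_group == "high_bias"]
  tab <- build_codon_table(seqs$cds, hi)
  usage <- sim_codon_usage("high_bias")
  sc <- mztseq:::sense_codons()
  # within multi-codon families the empirical frequencies track the
  # generating usage (multinomial error at ~60k codons)
  fams <- names(table(sc))[table(sc) > 1]
  for (aa in fams[1:5]) {
    fam <- names(sc)[sc == aa]
    emp <- tab$counts[fam] / sum(tab$counts[fam])
    expect_equal(unname(emp), unname(usage[fam]), tolerance = 0.05)
  }
})

test_that("build_codon_table validates its reference set", {
  good <- setNames(rep("ATGAATTAA", 12), sprintf("g%d", 1:12))
  bad_stop <- c(bad = "ATGTAAAATTAA")   # internal stop
  bad_char <- c(badc = "ATGANTTAA")
  expect_warning(build_codon_table(c(good, bad_stop)), "internal stop")
  expect_warning(build_codon_table(c(good, bad_char)), "invalid CDS")
  expect_error(suppressWarnings(build_codon_table(good[1:5])),
               "fewer than 10")
})

test_that("CAI is the geometric mean over informative codons", {
  # two-codon CDS with w 0.5 and 0.125 -> sqrt(0.0625) = 0.25
  sc <- mztseq:::sense_codons()
  tab <- structure(list(
    counts = setNames(rep(1, length(sc)), names(sc)),
    freq = setNames(rep(1 / length(sc), length(sc)), names(sc)),
    w = setNames(rep(1, length(sc)), names(sc)), n_genes = 10),
    class = "codon_table")
  tab$w["AAT"] <- 0.5
  tab$w["GGT"] <- 0.125
  expect_equal(cai("ATGAATGGTTAA", tab), 0.25)

  # all-optimal CDS scores exactly 1
  cds_opt <- "ATGAAAGATTGTTAA"
  tab1 <- tab
  tab1$w[] <- 1
  expect_equal(cai(cds_opt, tab1), 1)

  # start codon and single-codon families are excluded from the mean
  tab2 <- tab1
  tab2$w["ATG"] <- 0.01   # must not matter: initiation + Met excluded
  tab2$w["TGG"] <- 0.01   # Trp excluded
  expect_equal(cai("ATGTGGAAATAA", tab2), 1)

  expect_error(cai("ATGTAA", tab1), "no codons")
})

test_that("CAI is order-invariant and concatenation-bounded", {
  cfg <- simulation_config(n_genes = 150, seed = 18)
  truth <- simulate_truth(cfg)
  seqs <- simulate_sequences(truth, cfg)
  tab <- build_codon_table(seqs$cds)
  s <- seqs$cds[[1]]
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  set.seed(1)
  inner <- cods[2:(length(cods) - 1)]
  perm <- paste0(cods[1], paste(sample(inner), collapse = ""),
                 cods[length(cods)])
  expect_equal(cai(s, tab), cai(perm, tab))

  a <- seqs$cds[[1]]
  b <- seqs$cds[[2]]
  joined <- paste0(substr(a, 1, nchar(a) - 3), substring(b, 4))
  ab <- sort(c(cai(a, tab), cai(b, tab)))
  expect_gte(cai(joined, tab), ab[1] * 0.999)
  expect_lte(cai(joined, tab), ab[2] * 1.001)
})

test_that("CAI separates the simulated bias groups", {
  cfg <- simulation_config(n_genes = 300, seed = 19)
  truth <- simulate_truth(cfg)
  seqs <- simulate_sequences(truth, cfg)
  g <- truth$genes
  egg <- setNames(g$A0, g$gene_id)
  ref <- select_cai_reference(egg, g$gene_id[g$class == "stable_maternal"],
                              top_n = 100)
  expect_lte(length(ref), 100)
  tab <- build_codon_table(seqs$cds, ref)
  vals <- cai(seqs$cds, tab)
  hi <- vals[g$codon_group == "high_bias"]
  lo <- vals[g$codon_group == "low_bias"]
  # AUC of the group separation
  auc <- mean(outer(hi, lo, ">")) + 0.5 * mean(outer(hi, lo, "=="))
  expect_gt(auc, 0.9)
})

test_that("3'UTR extraction keeps >20 nt and honors strand", {
  tx <- c(short = paste0(strrep("A", 30), strrep("G", 20)),
          keep = paste0(strrep("A", 30), strrep("G", 21)),
          minus = NA)
  utr_sense <- paste0("ACGTT", strrep("CT", 10))   # 25 nt
  body <- strrep("A", 40)
  tx["minus"] <- mztseq:::revcomp(paste0(body, utr_sense))
  cds_end <- c(short = 30, keep = 30, minus = 40)
  utrs <- extract_3utrs(tx, cds_end,
                        strand = c(short = "+", keep = "+", minus = "-"))
  expect_false("short" %in% names(utrs))           # exactly 20 nt discarded
  expect_identical(unname(utrs["keep"]), strrep("G", 21))
  expect_identical(unname(utrs["minus"]), utr_sense)
  expect_warning(extract_3utrs(tx, cds_end[1:2]), "no CDS end")
})
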