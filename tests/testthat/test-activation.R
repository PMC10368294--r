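# Genome-activation calling: intron table construction, the activation
# thresholds, categorization, and the window scan.

mk_cm <- function(counts, protocol = "ribo", time = 4) {
  meta <- data.frame(sample_id = colnames(counts), timepoint_hpf = time,
                     protocol = protocol, condition = "untreated",
                     replicate = seq_len(ncol(counts)))
  count_matrix(counts, meta)
}

test_that("intron counts subtract, clamp, and apply the RPKM gate", {
  # s1 exercises subtraction/clamping; s2 keeps g2 above the gate in at
  # least one sample (exclusion requires failing everywhere)
  pre <- matrix(c(100L, 60L, 1L, 100L, 300L, 1L), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ex <- matrix(c(60L, 70L, 0L, 60L, 50L, 1L), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  # s1 library total = 161; give g3 an intron length that puts its s1 RPKM
  # at exactly the 0.5 threshold: 1 / ((L/1e3) * (161/1e6)) = 0.5
  l3 <- 2e9 / 161
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    scaffold = "sc", strand = "+",
    start = c(1, 3001, 10001, 12001, 20001, 20001 + 1000 + l3),
    end = c(1000, 4000, 11000, 13000, 21000, 21000 + 1000 + l3))
  gm <- gene_models(exons)
  expect_message(
    ic <- build_intron_counts(mk_cm(pre), mk_cm(ex), gm, rpkm_min = 0.5),
    "clamped 1")
  expect_equal(unname(ic$counts["g1", "s1"]), 40L)   # 100 - 60
  expect_equal(unname(ic$counts["g2", "s1"]), 0L)    # clamped
  expect_equal(unname(ic$counts["g2", "s2"]), 250L)
  expect_true("g3" %in% rownames(ic$counts))  # s1 RPKM exactly 0.5 retained
  expect_equal(unname(ic$rpkm["g3", "s1"]), 0.5, tolerance = 1e-6)

  # gene failing the gate in every sample is excluded
  ic2 <- build_intron_counts(mk_cm(pre), mk_cm(ex), gm, rpkm_min = 1e6)
  expect_equal(nrow(ic2$counts), 0)
  expect_equal(ic2$excluded_low_rpkm, 3)

  bad <- mk_cm(ex[, 1, drop = FALSE])
  colnames(bad$counts) <- "other"
  bad$meta$sample_id <- "other"
  expect_error(build_intron_counts(mk_cm(pre), bad, gm), "same samples")
})

test_that("intronless genes never enter the intron table", {
  pre <- matrix(c(50L), 1, 1, dimnames = list("g1", "s1"))
  ex <- matrix(c(10L), 1, 1, dimnames = list("g1", "s1"))
  gm <- gene_models(data.frame(gene_id = "g1", scaffold = "s", strand = "+",
                               start = 1, end = 500))
  ic <- build_intron_counts(mk_cm(pre), mk_cm(ex), gm)
  expect_equal(nrow(ic$counts), 0)
  expect_equal(ic$excluded_intronless, 1)
})

test_that("exonic activation applies strict fold, padj, TPM and protocol", {
  de <- data.frame(gene_id = c("up", "exact2", "weak", "down"),
                   baseMean = 100,
                   log2FoldChange = c(3, 1, 3, -3),
                   pvalue = c(1e-9, 1e-9, 0.5, 1e-9),
                   padj = c(1e-8, 1e-8, 0.8, 1e-8),
                   filtered = FALSE)
  attr(de, "protocol") <- "ribo"
  tpm <- matrix(10, 4, 1, dimnames = list(de$gene_id, "4"))
  calls <- call_exonic_activation(list(`4` = de), tpm)
  expect_identical(calls$gene_id, "up")   # fold exactly 2 is NOT called

  tpm_low <- tpm
  tpm_low["up", ] <- 0.5                  # fails TPM > 1
  expect_equal(nrow(call_exonic_activation(list(`4` = de), tpm_low)), 0)

  attr(de, "protocol") <- "polyA"
  expect_error(call_exonic_activation(list(`4` = de), tpm),
               "rRNA-depleted")
})

test_that("intron activation reads the @intron entries of a joint table", {
  de <- data.frame(
    gene_id = c("g1@exon", "g1@intron", "g2@exon", "g2@intron"),
    baseMean = 50,
    log2FoldChange = c(0.1, 4, 0.2, -2),
    pvalue = c(0.9, 1e-9, 0.7, 1e-9),
    padj = c(0.95, 1e-8, 0.9, 1e-8),
    filtered = FALSE)
  calls <- call_intron_activation(list(`4` = de))
  expect_identical(calls$gene_id, "g1")   # positive-fold intron entry only
  expect_identical(calls$evidence, "intron")
})

test_that("categorization is a total function applying the TPM gates", {
  egg <- c(denovo = 0.2, react = 30, amb = 0.7, silent = 0.3, mat = 12)
  excall <- data.frame(gene_id = c("denovo", "amb"), timepoint = c(4, 4),
                       evidence = "exon")
  incall <- data.frame(gene_id = "react", timepoint = 4,
                       evidence = "intron")
  cats <- categorize_genes(egg, excall, incall, timepoints = c(3, 4))
  get <- function(g, t) cats$category[cats$gene_id == g & cats$timepoint == t]
  expect_identical(get("denovo", 4), "de_novo_zygotic")
  expect_identical(get("react", 4), "maternal_reactivated")
  expect_identical(get("amb", 4), "ambiguous")
  expect_identical(get("silent", 4), "not_expressed")
  expect_identical(get("mat", 4), "maternal_only")
  # before the calls, activated genes are still unactivated categories
  expect_identical(get("denovo", 3), "not_expressed")
  expect_identical(get("react", 3), "maternal_only")
  # exactly one category per gene per timepoint
  expect_equal(nrow(cats), length(egg) * 2)
  expect_false(anyNA(cats$category))
})

test_that("window scan is zero for identical libraries and log2 for folds", {
  gm <- gene_models(data.frame(
    gene_id = c("a", "b"), scaffold = "sc", strand = "+",
    start = c(1, 15001), end = c(2000, 17000)))
  w1 <- bin_counts_by_window(gm, c(a = 1000, b = 1000))
  ws0 <- window_scan(w1, w1)
  expect_true(all(ws0$log2fc == 0))

  # 4x RPM increase in window 'b' against a large stable background
  gm2 <- gene_models(data.frame(
    gene_id = c("a", "b", "bg"), scaffold = c("sc", "sc", "sc2"),
    strand = "+", start = c(1, 15001, 1), end = c(2000, 17000, 9000)))
  egg <- bin_counts_by_window(gm2, c(a = 1000, b = 250, bg = 1e6))
  t4 <- bin_counts_by_window(gm2, c(a = 1000, b = 1000, bg = 1e6))
  ws <- window_scan(t4, egg, pseudocount = 0.01)
  fc_b <- ws$log2fc[ws$genes == "b"]
  expect_equal(fc_b, 2, tolerance = 0.01)
  expect_error(bin_counts_by_window(gm2, c(a = 1), window_size = 0),
               "positive")
})

test_that("histone-like clusters dominate the top activation windows", {
  cfg <- simulation_config(n_genes = 500, library_depth = 3e5, seed = 21)
  truth <- simulate_truth(cfg)
  cts <- simulate_counts(truth, cfg)
  gm <- gene_models(truth_exons(truth))
  ribo <- cm_select(cts$ribo, condition = "untreated")
  meta <- ribo$meta
  cnt <- function(t) rowSums(ribo$counts[, meta$timepoint_hpf == t,
                                         drop = FALSE])
  ws <- window_scan(bin_counts_by_window(gm, cnt(4)),
                    bin_counts_by_window(gm, cnt(0)))
  top <- ws[ws$log2fc > log2(3), ]
  expect_gt(nrow(top), 0)
  # every histone-cluster window sits among the strongly activated windows
  hist_w <- ws[ws$scaffold == "HyShist", ]
  expect_true(all(hist_w$log2fc > log2(3)))
})
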