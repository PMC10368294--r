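# Forward simulator: configuration contracts, determinism, class
# apportionment, the capture model, count moments and protocol contrast,
# conservation, and the implanted sequence features.

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(class_fractions = c(stable_maternal = 1)),
               "class_fractions")
  fr <- mztseq:::default_class_fractions
  fr["stable_maternal"] <- fr["stable_maternal"] + 0.1
  expect_error(simulation_config(class_fractions = fr), "sum to 1")
  expect_error(simulation_config(timepoints = c(0, 2, 2)), "increasing")
  expect_error(simulation_config(library_depth = 0), "depth")
  expect_error(simulation_config(mirna_len = 17), "18, 25")
  expect_error(simulation_config(nascent_intron_fraction = 1.5), "\\[0, 1\\]")
})

test_that("capture probability follows the Hill form", {
  expect_equal(capture_probability(0), 0)
  expect_equal(capture_probability(30, K = 30), 0.5)
  expect_equal(capture_probability(90, K = 30, h = 2), 0.9)
  L <- seq(0, 200, by = 5)
  expect_true(all(diff(capture_probability(L)) >= 0))
  expect_true(all(capture_probability(L) >= 0 & capture_probability(L) < 1))
  expect_error(capture_probability(-1), "non-negative")
})

test_that("truth simulation is deterministic and apportions classes", {
  cfg <- simulation_config(n_genes = 200, seed = 4)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)

  # exact apportionment within 1 of fractions * n
  tab <- table(t1$genes$class)
  expectn <- cfg$class_fractions[names(tab)] * cfg$n_genes
  expect_true(all(abs(tab - expectn) <= 1))

  fr <- setNames(rep(0, length(mztseq:::sim_classes)),
                 mztseq:::sim_classes)
  fr["stable_maternal"] <- 0.5
  fr["de_novo_zygotic"] <- 0.5
  cfg2 <- simulation_config(n_genes = 1000, class_fractions = fr, seed = 1,
                            n_mirna = 0)
  t3 <- simulate_truth(cfg2)
  expect_true(abs(sum(t3$genes$class == "stable_maternal") - 500) <= 1)

  # degenerate single-class simulation: everything constant
  fr1 <- setNames(rep(0, length(mztseq:::sim_classes)),
                  mztseq:::sim_classes)
  fr1["stable_maternal"] <- 1
  cfg1 <- simulation_config(n_genes = 50, class_fractions = fr1, seed = 2,
                            n_mirna = 0, histone_share = 0)
  ts <- simulate_truth(cfg1)
  expect_true(all(ts$A == ts$A[, 1]))
  expect_true(all(ts$L == ts$L[, 1]))
})

test_that("decay onsets follow deadenylation for the two-step class", {
  cfg <- simulation_config(n_genes = 400, seed = 8)
  g <- simulate_truth(cfg)$genes
  dtd <- g[g$class == "deadenylated_then_degraded", ]
  expect_gt(nrow(dtd), 0)
  expect_true(all(dtd$t_decay > dtd$deaden_onset))
})

test_that("counts respect conservation and the protocol contrast", {
  # many replicates to measure expectations; the protocol contrast is the
  # poly(A)-capture signal the clearance analysis formalizes
  fr <- setNames(rep(0, length(mztseq:::sim_classes)), mztseq:::sim_classes)
  fr["stable_maternal"] <- 0.5
  fr["deadenylated_only"] <- 0.5
  cfg <- simulation_config(n_genes = 40, class_fractions = fr,
                           replicates = 200, library_depth = 2e5,
                           timepoints = c(0, 4, 7), deaden_onset = 3,
                           n_mirna = 0, histone_share = 0, seed = 6)
  truth <- simulate_truth(cfg)
  cts <- simulate_counts(truth, cfg)
  expect_true(all(cts$exon$counts <= cts$premrna$counts))
  expect_true(all(cts$polyA$counts >= 0))

  g <- truth$genes
  da <- g$gene_id[g$class == "deadenylated_only"]
  ribo <- cts$ribo
  m_ribo <- expression_by_time(ribo$counts, ribo)
  m_polya <- expression_by_time(cts$polyA$counts, cts$polyA)
  # mean ribo counts at the last timepoint within 10% of egg level
  expect_true(all(abs(m_ribo[da, "7"] / m_ribo[da, "0"] - 1) < 0.1))
  # mean polyA counts >= 2-fold lower after the tail drop
  expect_true(all(m_polya[da, "7"] / m_polya[da, "0"] < 0.5))
})

test_that("dispersion zero gives Poisson-scale noise for a stable gene", {
  fr <- setNames(rep(0, length(mztseq:::sim_classes)), mztseq:::sim_classes)
  fr["stable_maternal"] <- 1
  cfg <- simulation_config(n_genes = 20, class_fractions = fr,
                           nb_dispersion = 0, replicates = 300,
                           timepoints = c(0, 7), library_depth = 1e5,
                           n_mirna = 0, histone_share = 0, seed = 13)
  truth <- simulate_truth(cfg)
  cts <- simulate_counts(truth, cfg)
  egg <- cts$ribo$counts[, cts$ribo$meta$timepoint_hpf == 0 &
                           cts$ribo$meta$condition == "untreated"]
  vm <- apply(egg, 1, var) / rowMeans(egg)
  # variance/mean ratio concentrates around 1 under Poisson sampling
  expect_true(all(vm > 0.7 & vm < 1.4))
})

test_that("triptolide zeroes zygotic components in the truth", {
  cfg <- simulation_config(n_genes = 300, seed = 5)
  truth <- simulate_truth(cfg)
  g <- truth$genes
  dn <- g$class == "de_novo_zygotic"
  expect_true(all(truth$A_trip[dn, ] == 0))
  # late decay is transcription-dependent: suppressed under inhibition
  late <- g$class == "mirna_target"
  expect_true(all(truth$A_trip[late, ncol(truth$A_trip)] ==
                    g$A0[late]))
  expect_true(all(truth$I_trip[dn, ncol(truth$I_trip)] == 0))
})

test_that("simulated sequences carry the designed implants", {
  cfg <- simulation_config(n_genes = 200, seed = 10, target_site_mismatch = 0,
                           target_site_gu = 0)
  truth <- simulate_truth(cfg)
  seqs <- simulate_sequences(truth, cfg)
  mt <- seqs$mirna_truth
  expect_equal(nrow(mt), cfg$n_mirna)
  for (r in seq_len(nrow(mt))) {
    tx <- seqs$transcripts[[mt$host_gene[r]]]
    mat_dna <- chartr("U", "T", mt$mature[r])
    expect_identical(substring(tx, mt$mature_start[r], mt$mature_end[r]),
                     mat_dna)
    # the folding DP recovers a deep stem at the implant
    hp <- substring(tx, mt$hairpin_start[r], mt$hairpin_end[r])
    expect_gte(fold_hairpin(hp)$n_pairs, 14)
  }
  tt <- seqs$target_truth
  real <- tt[!tt$decoy, ]
  for (r in seq_len(nrow(real))) {
    tx <- seqs$transcripts[[real$gene_id[r]]]
    site <- substring(tx, real$site_start[r], real$site_end[r])
    mat <- chartr("U", "T", mt$mature[mt$mirna_id == real$mirna_id[r]])
    # zero mismatches / zero wobbles: the site is the exact reverse complement
    expect_identical(site, mztseq:::revcomp(mat))
  }
  # CDS are translatable frames with terminal stop only
  cds <- seqs$cds[1:20]
  expect_true(all(nchar(cds) %% 3 == 0))
  aa <- vapply(cds, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, character(1))
  expect_true(all(substring(aa, nchar(aa)) == "*"))
  expect_false(any(grepl("\\*.", aa)))
})

test_that("count matrices round-trip through TSV", {
  cfg <- simulation_config(n_genes = 60, library_depth = 5e4, seed = 20)
  cts <- simulate_counts(simulate_truth(cfg), cfg)
  tmp <- tempfile()
  write_count_matrix(cts$ribo, paste0(tmp, ".tsv"), paste0(tmp, "_meta.tsv"))
  back <- read_count_matrix(paste0(tmp, ".tsv"), paste0(tmp, "_meta.tsv"))
  expect_identical(back$counts, cts$ribo$counts)
  expect_identical(back$meta$sample_id, cts$ribo$meta$sample_id)
})
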