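# Orchestration: configuration, per-stage runners over a run directory, and
# the end-to-end demo on generated data. Every stage reads its declared
# inputs from the run directory and writes TSV/FASTA/JSON outputs, so stages
# are runnable independently and reruns with the same seed are byte-identical.

#' Pipeline configuration
#'
#' Collects every analysis threshold (defaults are the study values used
#' throughout the package) plus the simulation size used by the `simulate`
#' and `demo` stages. Round-trips losslessly through YAML.
#'
#' @param seed master seed.
#' @param n_genes,library_depth,replicates simulation size for
#'   simulate/demo runs.
#' @param padj_max,activation_fold,tpm_min,denovo_egg_tpm,intron_rpkm,
#'   clearance_fold,oscillation_rise,stability_fold,cai_top_n,utr_min_len,
#'   mirna_word_size,target_word_size,max_mismatch,min_paired_fraction,
#'   stem_min,trim_band analysis thresholds; see the stage functions.
#' @param triptolide_null generate a null (no-effect) triptolide condition.
#' @return list of class `mzt_config`.
#' @export
pipeline_config <- function(seed = 1, n_genes = 300, library_depth = 2e5,
                            replicates = 2, padj_max = 0.05,
                            activation_fold = 2, tpm_min = 1,
                            denovo_egg_tpm = 0.5, intron_rpkm = 0.5,
                            clearance_fold = 2, oscillation_rise = 1.5,
                            stability_fold = 1.25, cai_top_n = 100,
                            utr_min_len = 20, mirna_word_size = 7,
                            target_word_size = 4, max_mismatch = 2,
                            min_paired_fraction = 0.85, stem_min = 14,
                            trim_band = c(0.1, 0.9),
                            triptolide_null = FALSE) {
  cfg <- as.list(environment())
  ranges <- list(padj_max = c(0, 1), min_paired_fraction = c(0, 1),
                 denovo_egg_tpm = c(0, Inf), activation_fold = c(1, Inf),
                 clearance_fold = c(1, Inf), oscillation_rise = c(1, Inf),
                 stability_fold = c(1, Inf))
  for (nm in names(ranges))
    if (cfg[[nm]] < ranges[[nm]][1] || cfg[[nm]] > ranges[[nm]][2])
      stopf("config field %s out of range", nm)
  class(cfg) <- "mzt_config"
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config an [pipeline_config()] object.
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns an `mzt_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

inp <- function(dir, ...) file.path(dir, "inputs", ...)

load_inputs <- function(dir) {
  if (!file.exists(inp(dir, "ribo_counts.tsv")))
    stopf("missing input: %s (run the simulate stage first)",
          inp(dir, "ribo_counts.tsv"))
  list(
    polya = read_count_matrix(inp(dir, "polyA_counts.tsv"),
                              inp(dir, "polyA_meta.tsv")),
    ribo = read_count_matrix(inp(dir, "ribo_counts.tsv"),
                             inp(dir, "ribo_meta.tsv")),
    exon = read_count_matrix(inp(dir, "exon_counts.tsv"),
                             inp(dir, "ribo_meta.tsv")),
    premrna = read_count_matrix(inp(dir, "premrna_counts.tsv"),
                                inp(dir, "ribo_meta.tsv")),
    models = read_gene_models(inp(dir, "models.gtf")),
    truth = read_tsv(inp(dir, "truth_genes.tsv")),
    class_map = read_tsv(inp(dir, "class_map.tsv")),
    go_map = read_tsv(inp(dir, "go_map.tsv")),
    transcripts = read_fasta(inp(dir, "transcripts.fa")),
    cds = read_fasta(inp(dir, "cds.fa")),
    refs = read_fasta(inp(dir, "mirna_refs.fa")))
}

sim_config_from <- function(config) {
  simulation_config(n_genes = config$n_genes,
                    library_depth = config$library_depth,
                    replicates = config$replicates,
                    triptolide_null = config$triptolide_null,
                    seed = config$seed)
}

stage_simulate <- function(config, dir) {
  dir.create(inp(dir), recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_mzt(sim_config_from(config))
  write_count_matrix(sim$counts$polyA, inp(dir, "polyA_counts.tsv"),
                     inp(dir, "polyA_meta.tsv"))
  write_count_matrix(sim$counts$ribo, inp(dir, "ribo_counts.tsv"),
                     inp(dir, "ribo_meta.tsv"))
  write_tsv(data.frame(gene_id = rownames(sim$counts$exon$counts),
                       sim$counts$exon$counts, check.names = FALSE),
            inp(dir, "exon_counts.tsv"))
  write_tsv(data.frame(gene_id = rownames(sim$counts$premrna$counts),
                       sim$counts$premrna$counts, check.names = FALSE),
            inp(dir, "premrna_counts.tsv"))
  write_gtf(sim$exons, inp(dir, "models.gtf"))
  write_fasta(sim$seqs$transcripts, inp(dir, "transcripts.fa"))
  write_fasta(sim$seqs$cds, inp(dir, "cds.fa"))
  write_fasta(sim$seqs$utr3, inp(dir, "utr3.fa"))
  write_fasta(sim$seqs$mirna_refs, inp(dir, "mirna_refs.fa"))
  g <- sim$truth$genes
  write_tsv(g, inp(dir, "truth_genes.tsv"))
  # histone class map: cycle the five classes over the histone-like genes
  hist_genes <- g$gene_id[g$class == "histone_like"]
  cmap <- data.frame(
    gene_id = hist_genes,
    class = rep_len(c("H1", "H2A", "H2B", "H3", "H4"), length(hist_genes)))
  write_tsv(cmap, inp(dir, "class_map.tsv"))
  # toy GO map: class-linked terms plus a broad background term
  go <- rbind(
    data.frame(gene_id = hist_genes, term = "GO:chromatin_assembly"),
    data.frame(gene_id = g$gene_id[g$class == "de_novo_zygotic"],
               term = "GO:zygotic_program"),
    data.frame(gene_id = g$gene_id[seq(1, nrow(g), by = 3)],
               term = "GO:housekeeping"))
  write_tsv(go, inp(dir, "go_map.tsv"))
  jsonlite::write_json(
    list(config = unclass(sim$truth$config),
         mirna_truth = sim$seqs$mirna_truth,
         target_truth = sim$seqs$target_truth),
    inp(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE)
  invisible(dir)
}

de_long <- function(de_by_time) {
  do.call(rbind, lapply(names(de_by_time), function(tn)
    cbind(timepoint = as.numeric(tn), as.data.frame(de_by_time[[tn]]))))
}

stage_de <- function(config, dir) {
  x <- load_inputs(dir)
  dir.create(file.path(dir, "de"), showWarnings = FALSE)
  for (prot in c("polyA", "ribo")) {
    cm <- if (prot == "polyA") x$polya else x$ribo
    des <- de_series(cm_select(cm, condition = "untreated"), min_total = 10)
    write_tsv(de_long(des), file.path(dir, "de",
                                      paste0("de_", prot, ".tsv")))
  }
  # triptolide vs dmso per protocol at the treatment timepoint
  for (prot in c("polyA", "ribo")) {
    cm <- if (prot == "polyA") x$polya else x$ribo
    trip <- cm_samples(cm, condition = "triptolide")
    dmso <- cm_samples(cm, condition = "dmso")
    de <- nb_test(cm, dmso, trip, min_total = 10)
    write_tsv(as.data.frame(de),
              file.path(dir, "de", paste0("de_trip_", prot, ".tsv")))
  }
  invisible(dir)
}

stage_activation <- function(config, dir) {
  x <- load_inputs(dir)
  dir.create(file.path(dir, "activation"), showWarnings = FALSE)
  lens <- gene_lengths(x$models)
  ribo_un <- cm_select(x$ribo, condition = "untreated")
  tpm <- compute_tpm(ribo_un, lens)
  tpm_bt <- expression_by_time(tpm, ribo_un)
  des <- de_series(ribo_un, min_total = 10)
  ex_calls <- call_exonic_activation(des, tpm_bt,
                                     fold_min = config$activation_fold,
                                     padj_max = config$padj_max,
                                     tpm_min = config$tpm_min)
  exon_un <- cm_select(x$exon, condition = "untreated")
  prem_un <- cm_select(x$premrna, condition = "untreated")
  ic <- build_intron_counts(prem_un, exon_un, x$models,
                            rpkm_min = config$intron_rpkm)
  comb <- combine_exon_intron(exon_un, ic)
  des_comb <- de_series(comb, min_total = 10)
  in_calls <- call_intron_activation(des_comb, padj_max = config$padj_max)
  calls <- rbind(ex_calls, in_calls)
  write_tsv(calls, file.path(dir, "activation", "activation_calls.tsv"))
  egg <- tpm_bt[, 1]
  cats <- categorize_genes(setNames(egg, rownames(tpm_bt)), ex_calls,
                           in_calls, as.numeric(colnames(tpm_bt)[-1]))
  write_tsv(cats, file.path(dir, "activation", "categories.tsv"))
  # 10-kb window scan of the last timepoint against egg
  meta <- ribo_un$meta
  last_t <- max(meta$timepoint_hpf)
  cnt_at <- function(t) rowSums(ribo_un$counts[
    , meta$sample_id[meta$timepoint_hpf == t], drop = FALSE])
  w_t <- bin_counts_by_window(x$models, cnt_at(last_t))
  w_e <- bin_counts_by_window(x$models, cnt_at(min(meta$timepoint_hpf)))
  ws <- window_scan(w_t, w_e)
  write_tsv(ws, file.path(dir, "activation", "windows.tsv"))
  invisible(dir)
}

stage_clearance <- function(config, dir) {
  x <- load_inputs(dir)
  dir.create(file.path(dir, "clearance"), showWarnings = FALSE)
  lens <- gene_lengths(x$models)
  res <- run_clearance(x$polya, x$ribo, lens,
                       fold_min = config$clearance_fold,
                       padj_max = config$padj_max,
                       rise_max = config$oscillation_rise,
                       stability_fold = config$stability_fold)
  write_tsv(res$profiles, file.path(dir, "clearance", "profiles.tsv"))
  write_tsv(as.data.frame(res$matrix),
            file.path(dir, "clearance", "matrix.tsv"))
  write_tsv(data.frame(gene_id = res$stable_reference),
            file.path(dir, "clearance", "stable_reference.tsv"))
  jsonlite::write_json(res$triptolide, file.path(dir, "clearance",
                                                 "triptolide_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full clearance analysis in memory
#'
#' Convenience wrapper used by the clearance stage and by validation code:
#' computes per-protocol decrease series, clearance profiles and groups, the
#' stable reference set, and the triptolide transcription-dependence tests
#' for the early- and late-cleared groups.
#'
#' @param polya,ribo [count_matrix()] objects for the two protocols.
#' @param lengths gene lengths for TPM.
#' @param fold_min,padj_max,rise_max,stability_fold thresholds.
#' @return list with `profiles`, `matrix`, `modes`, `stable_reference`,
#'   `triptolide` (per-group test results or the error message).
#' @export
run_clearance <- function(polya, ribo, lengths, fold_min = 2,
                          padj_max = 0.05, rise_max = 1.5,
                          stability_fold = 1.25) {
  polya_un <- cm_select(polya, condition = "untreated")
  ribo_un <- cm_select(ribo, condition = "untreated")
  tps <- sort(unique(polya_un$meta$timepoint_hpf))
  scan_t <- tps[tps >= 2]
  de_p <- de_series(polya_un, times = scan_t, min_total = 10)
  de_r <- de_series(ribo_un, times = scan_t, min_total = 10)
  fd_p <- first_decrease(de_p, fold_min = fold_min, padj_max = padj_max)
  fd_r <- first_decrease(de_r, fold_min = fold_min, padj_max = padj_max)
  tpm_p <- compute_tpm(polya_un, lengths)
  tpm_r <- compute_tpm(ribo_un, lengths)
  bt_p <- expression_by_time(tpm_p, polya_un)
  bt_r <- expression_by_time(tpm_r, ribo_un)
  maternal <- rownames(bt_r)[bt_r[, 1] >= 1]
  prof <- clearance_profiles(fd_p, fd_r, bt_p, maternal)
  cmx <- clearance_matrix(prof, timepoints = scan_t)
  modes <- classify_clearance_mode(prof)
  tpm_p_all <- compute_tpm(polya, lengths)
  trip_de_p <- tryCatch(nb_test(polya, cm_samples(polya, condition = "dmso"),
                                cm_samples(polya, condition = "triptolide"),
                                min_total = 10),
                        error = function(e) NULL)
  stable_ref <- if (!is.null(trip_de_p))
    stable_reference_set(bt_p, trip_de_p, maternal,
                         fold_max = stability_fold, padj_max = padj_max)
  else character(0)
  tpm_r_all <- compute_tpm(ribo, lengths)
  trip_tests <- list()
  if (any(ribo$meta$condition == "triptolide")) {
    fc_tr <- tpm_fold_change(tpm_r_all, ribo, "triptolide")
    fc_dm <- tpm_fold_change(tpm_r_all, ribo, "dmso")
    for (grp in c("early", "late")) {
      genes <- prof$gene_id[prof$group == grp]
      trip_tests[[grp]] <- tryCatch(
        triptolide_effect(fc_tr, fc_dm, genes),
        error = function(e) list(error = conditionMessage(e)))
    }
  }
  list(profiles = prof, matrix = cmx, modes = modes,
       stable_reference = stable_ref, triptolide = trip_tests)
}

stage_cai <- function(config, dir) {
  x <- load_inputs(dir)
  dir.create(file.path(dir, "cai"), showWarnings = FALSE)
  lens <- gene_lengths(x$models)
  res <- run_clearance(x$polya, x$ribo, lens,
                       fold_min = config$clearance_fold,
                       padj_max = config$padj_max)
  ribo_un <- cm_select(x$ribo, condition = "untreated")
  tpm_bt <- expression_by_time(compute_tpm(ribo_un, lens), ribo_un)
  stable <- res$profiles$gene_id[res$profiles$group == "stable"]
  ref <- select_cai_reference(setNames(tpm_bt[, 1], rownames(tpm_bt)),
                              stable, top_n = config$cai_top_n)
  tab <- build_codon_table(x$cds, ref)
  vals <- cai(x$cds, tab)
  write_tsv(data.frame(gene_id = names(vals), cai = unname(vals),
                       n_codons = nchar(x$cds) / 3 - 2),
            file.path(dir, "cai", "cai.tsv"))
  write_tsv(data.frame(codon = names(tab$w), count = unname(tab$counts),
                       freq = unname(tab$freq), w = unname(tab$w)),
            file.path(dir, "cai", "codon_table.tsv"))
  # 3'UTR sets for external motif tools: cleared foreground, stable control
  utrs <- extract_3utrs(x$transcripts,
                        setNames(50 + nchar(x$cds), names(x$cds)),
                        min_len_exclusive = config$utr_min_len)
  cleared <- res$profiles$gene_id[res$profiles$group %in% c("early", "late")]
  fg <- utrs[names(utrs) %in% cleared]
  bg <- utrs[names(utrs) %in% stable]
  if (length(fg)) write_fasta(fg, file.path(dir, "cai", "utr3_cleared.fa"))
  if (length(bg)) write_fasta(bg, file.path(dir, "cai", "utr3_stable.fa"))
  invisible(dir)
}

stage_mirna <- function(config, dir) {
  x <- load_inputs(dir)
  dir.create(file.path(dir, "mirna"), showWarnings = FALSE)
  ribo_un <- cm_select(x$ribo, condition = "untreated")
  des <- de_series(ribo_un, min_total = 10)
  trip_de <- nb_test(x$ribo, cm_samples(x$ribo, condition = "dmso"),
                     cm_samples(x$ribo, condition = "triptolide"),
                     min_total = 10)
  hits <- scan_reference_mirnas(x$refs, x$transcripts,
                                word_size = config$mirna_word_size,
                                max_mismatch = config$max_mismatch)
  cands <- mirna_candidates(hits, x$transcripts,
                            stem_min = config$stem_min)
  kept <- filter_candidates(cands, des, trip_de,
                            padj_max = config$padj_max)
  write_tsv(kept, file.path(dir, "mirna", "candidates.tsv"))
  lens <- gene_lengths(x$models)
  res <- run_clearance(x$polya, x$ribo, lens,
                       fold_min = config$clearance_fold,
                       padj_max = config$padj_max)
  cleared <- res$profiles$gene_id[res$profiles$group %in% c("early", "late")]
  stable <- res$profiles$gene_id[res$profiles$group == "stable"]
  matures <- setNames(kept$mature, paste0(kept$ref_id, "@",
                                          kept$transcript_id))
  tg <- predict_targets(matures, x$transcripts[cleared],
                        x$transcripts[stable],
                        word_size = config$target_word_size,
                        min_paired_fraction = config$min_paired_fraction)
  write_tsv(tg, file.path(dir, "mirna", "targets.tsv"))
  invisible(dir)
}

stage_histone <- function(config, dir) {
  x <- load_inputs(dir)
  dir.create(file.path(dir, "histone"), showWarnings = FALSE)
  lens <- gene_lengths(x$models)
  ribo_un <- cm_select(x$ribo, condition = "untreated")
  tpm <- compute_tpm(ribo_un, lens)
  cp <- class_proportions(tpm, ribo_un, x$class_map)
  write_tsv(cp, file.path(dir, "histone", "class_proportions.tsv"))
  hmap <- data.frame(gene_id = x$class_map$gene_id, class = "histone")
  na <- net_activation(ribo_un, class_map = hmap, trimmed = TRUE,
                       trim = config$trim_band)
  write_tsv(na, file.path(dir, "histone", "net_activation.tsv"))
  invisible(dir)
}

stage_stages <- function(config, dir) {
  x <- load_inputs(dir)
  dir.create(file.path(dir, "stages"), showWarnings = FALSE)
  lens <- gene_lengths(x$models)
  polya_un <- cm_select(x$polya, condition = "untreated")
  tpm_bt <- expression_by_time(compute_tpm(polya_un, lens), polya_un)
  des <- de_series(polya_un, min_total = 10)
  sig <- unique(unlist(lapply(des, function(de)
    de$gene_id[!is.na(de$padj) & de$padj < config$padj_max])))
  calls <- call_stage_specific(tpm_bt, sig)
  write_tsv(calls, file.path(dir, "stages", "stage_calls.tsv"))
  qual <- calls[calls$qualifies, ]
  peaks <- setNames(qual$peak_stage, qual$gene_id)
  tps <- as.numeric(colnames(tpm_bt))
  pools <- list(egg = as.character(tps[tps < 1]),
                cleavage = as.character(tps[tps >= 1 & tps < 3]),
                blastula = as.character(tps[tps >= 3 & tps < 5]),
                gastrula = as.character(tps[tps >= 5 & tps < 7]),
                late = as.character(tps[tps >= 7]))
  grp <- pool_stages(peaks, pools)
  # an egg-to-gastrula run has no larval stages, so test across the pooled
  # groups that are actually populated (the 5-group layout needs later
  # timepoints; go_stage_enrichment defaults to requiring it)
  enr <- tryCatch(
    go_stage_enrichment(x$go_map, grp,
                        min_groups = min(5, length(unique(grp)))),
    error = function(e) data.frame(term = character(0),
                                   statistic = numeric(0), dof = integer(0),
                                   pvalue = numeric(0), padj = numeric(0)))
  write_tsv(enr, file.path(dir, "stages", "go_enrichment.tsv"))
  invisible(dir)
}

stage_registry <- function() {
  list(simulate = stage_simulate, de = stage_de,
       activation = stage_activation, clearance = stage_clearance,
       cai = stage_cai, mirna = stage_mirna, histone = stage_histone,
       stages = stage_stages)
}

#' Run one pipeline stage
#'
#' @param stage one of `simulate`, `de`, `activation`, `clearance`, `cai`,
#'   `mirna`, `histone`, `stages`, or `demo` (simulate + all stages +
#'   manifest).
#' @param config an [pipeline_config()].
#' @param outdir run directory.
#' @return the run directory, invisibly.
#' @export
run_stage <- function(stage, config = pipeline_config(), outdir) {
  reg <- stage_registry()
  stage <- match.arg(stage, c(names(reg), "demo"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "demo") return(run_demo(outdir, config))
  reg[[stage]](config, outdir)
  invisible(outdir)
}

#' Run the end-to-end demo on generated data
#'
#' Simulates a small dataset, runs every analysis stage, and writes a
#' machine-readable manifest (config copy, file list with MD5 checksums,
#' package version). With an identical seed/config, a rerun produces
#' byte-identical outputs.
#'
#' @param outdir run directory (created).
#' @param config an [pipeline_config()].
#' @return path of the manifest file, invisibly.
#' @export
run_demo <- function(outdir, config = pipeline_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(outdir, "config.yaml"))
  for (st in names(stage_registry())) {
    message("running stage: ", st)
    run_stage(st, config, outdir)
  }
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "mztseq",
    version = as.character(utils::packageVersion("mztseq")),
    config_hash = unname(tools::md5sum(file.path(outdir, "config.yaml"))),
    stages = names(stage_registry()),
    files = lapply(files, function(f) list(
      path = f, md5 = unname(tools::md5sum(file.path(outdir, f))))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(outdir, "manifest.json"))
}
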