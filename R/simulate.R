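# Forward simulator for a maternal-to-zygotic transition timecourse observed
# through paired poly(A)+ and rRNA-depleted RNA-seq. The generator produces
# expected-abundance / poly(A)-tail trajectories per gene class, draws
# negative-binomial counts per library, and emits gene models, sequences and
# the ground truth the analysis modules are validated against.

sim_classes <- c("stable_maternal", "readenylated", "deadenylated_only",
                 "deadenylated_then_degraded", "reactivated_maternal",
                 "de_novo_zygotic", "histone_like", "mirna_target")

default_class_fractions <- c(
  stable_maternal = 0.16, readenylated = 0.08, deadenylated_only = 0.08,
  deadenylated_then_degraded = 0.08, reactivated_maternal = 0.10,
  de_novo_zygotic = 0.46, histone_like = 0.02, mirna_target = 0.02)

#' Simulation configuration
#'
#' Defines the generative conditions of a simulated embryonic timecourse:
#' egg-inherited (maternal) mRNA spanning roughly half the genes, post-
#' fertilization poly(A)-tail changes (readenylation and staged
#' deadenylation) that alter poly(A)+ capture but not true abundance, delayed
#' zygotic genome activation visible mostly as intronic signal for maternal
#' genes, non-adenylated histone-like genes bursting to a configured share of
#' the transcriptome, delayed nucleolytic decay that is transcription-
#' dependent, and a transcription-inhibited (triptolide) condition sampled at
#' the last timepoint.
#'
#' @param n_genes number of genes.
#' @param timepoints strictly increasing timepoints in hours post
#'   fertilization; the first is the unfertilized egg.
#' @param replicates libraries per timepoint/protocol/condition.
#' @param library_depth expected reads per library.
#' @param nb_dispersion NB dispersion alpha (variance `m + alpha m^2`);
#'   0 gives Poisson counts.
#' @param tail_capture_K,tail_capture_h Hill half-saturation tail length (nt)
#'   and exponent of the poly(A)+ capture model, see
#'   [capture_probability()].
#' @param class_fractions named proportions over the eight gene classes;
#'   must sum to 1.
#' @param tail_long,tail_short,tail_egg_readenylated poly(A)-tail lengths
#'   (nt) for fully adenylated, deadenylated and pre-readenylation states.
#' @param deaden_onset,readen_onset,decay_onset,denovo_onset,
#'   reactivation_onset candidate onset timepoints (h.p.f.) sampled per gene.
#' @param decay_rate log2 abundance lost per hour once decay starts (the
#'   first decayed timepoint is already down by this factor).
#' @param reactivated_exon_boost,reactivated_intron_boost zygotic exonic and
#'   intronic signal of re-activated maternal genes, as multiples of the
#'   gene's maternal abundance.
#' @param nascent_intron_fraction intron signal of de novo zygotic genes as a
#'   fraction of their zygotic exonic signal.
#' @param intron_background baseline intronic signal of any intron-bearing
#'   gene, as a fraction of its abundance.
#' @param histone_share transcriptome share (TPM proportion) the histone-like
#'   class reaches at `histone_peak_time`.
#' @param histone_peak_time timepoint of the configured histone share.
#' @param maternal_sdlog,zygotic_sdlog lognormal spread of maternal
#'   abundances and zygotic amplitudes.
#' @param zygotic_amp_scale mean zygotic amplitude of de novo genes as a
#'   fraction of the mean maternal abundance; kept well below 1 so the
#'   adenylated transcript pool stays maternal-dominated through gastrulation
#'   (histone-like genes are calibrated separately via `histone_share`).
#' @param triptolide_null if `TRUE` the triptolide condition has no effect
#'   (samples are generated like DMSO); the null configuration for
#'   calibration experiments.
#' @param n_mirna number of implanted pri-miRNA hairpins (hosted in de novo
#'   zygotic genes).
#' @param mirna_len mature miRNA length (nt), must lie in `[18, 25]`.
#' @param hairpin_loop_len loop length of implanted hairpins.
#' @param ref_mismatch mismatches between each implanted mature sequence and
#'   its reference-set homolog (recycled over miRNAs).
#' @param target_site_mismatch,target_site_gu mismatches and G:U (wobble)
#'   conversions implanted in each target site.
#' @param decoy_mismatch mismatches of decoy sites implanted in stable
#'   maternal 3'UTRs (should exceed the detection threshold).
#' @param genes_per_scaffold gene count per simulated scaffold; histone-like
#'   genes are clustered on their own scaffold.
#' @param seed master seed; all randomness derives from it via [sub_seed()].
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(
    n_genes = 2000,
    timepoints = c(0, 0.5, 1, 2, 3, 4, 5, 6, 7),
    replicates = 2,
    library_depth = 1e6,
    nb_dispersion = 0.005,
    tail_capture_K = 30,
    tail_capture_h = 2,
    class_fractions = default_class_fractions,
    tail_long = 70,
    tail_short = 10,
    tail_egg_readenylated = 12,
    deaden_onset = c(2, 3, 4),
    readen_onset = c(0.5, 1),
    decay_onset = c(5, 6),
    denovo_onset = c(2, 3, 4),
    reactivation_onset = c(4, 5),
    decay_rate = 1.3,
    reactivated_exon_boost = 0.2,
    reactivated_intron_boost = 2,
    nascent_intron_fraction = 0.3,
    intron_background = 0.01,
    histone_share = 1 / 3,
    histone_peak_time = 4,
    maternal_sdlog = 1,
    zygotic_sdlog = 1,
    zygotic_amp_scale = 0.15,
    triptolide_null = FALSE,
    n_mirna = 4,
    mirna_len = 22,
    hairpin_loop_len = 8,
    ref_mismatch = c(0, 1, 2),
    target_site_mismatch = 1,
    target_site_gu = 1,
    decoy_mismatch = 5,
    genes_per_scaffold = 50,
    seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- cfg$class_fractions
  if (!setequal(names(fr), sim_classes))
    stopf("class_fractions must name exactly: %s",
          paste(sim_classes, collapse = ", "))
  if (abs(sum(fr) - 1) > 1e-9) stopf("class_fractions must sum to 1")
  if (any(fr < 0)) stopf("class_fractions must be non-negative")
  if (any(diff(cfg$timepoints) <= 0))
    stopf("timepoints must be strictly increasing")
  if (cfg$library_depth <= 0) stopf("library_depth must be positive")
  if (cfg$nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (cfg$mirna_len < 18 || cfg$mirna_len > 25)
    stopf("mature miRNA length must lie in [18, 25] nt")
  for (f in c("nascent_intron_fraction", "intron_background",
              "histone_share"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must lie in [0, 1]", f)
  if (cfg$n_genes < length(sim_classes))
    stopf("n_genes too small for the class mix")
  if (cfg$histone_peak_time <= 2)
    stopf("histone_peak_time must be after the 2 h.p.f. onset")
  invisible(cfg)
}

#' Poly(A)+ capture probability of a tail length
#'
#' Hill saturation `L^h / (L^h + K^h)`: monotone non-decreasing in the tail
#' length `L`, 0 at `L = 0`, one half at `L = K`, and strictly below 1. This
#' is the only place tail length enters the observation model: poly(A)+
#' counts are proportional to abundance times capture, rRNA-depleted counts
#' to abundance alone.
#'
#' @param tail_length poly(A)-tail length in nt, `>= 0`.
#' @param K half-saturation tail length (nt).
#' @param h Hill exponent.
#' @return capture probability in `[0, 1)`.
#' @export
capture_probability <- function(tail_length, K = 30, h = 2) {
  if (any(tail_length < 0)) stopf("tail length must be non-negative")
  if (K <= 0 || h <= 0) stopf("K and h must be positive")
  lh <- tail_length^h
  ifelse(tail_length == 0, 0, lh / (lh + K^h))
}

# zygotic ramp: 0 before onset, half at the onset timepoint, full afterwards
zyg_ramp <- function(t, t_on) {
  ifelse(is.na(t_on) | t < t_on, 0, pmin(1, (t - t_on + 1) / 2))
}

# histone activation profile: onset at 2 h.p.f., saturating by the peak time
histone_ramp <- function(t, peak) {
  approx(x = c(0, 2, (2 + peak) / 2, peak, peak + 100),
         y = c(0, 0.1, 0.5, 1, 1),
         xout = pmin(t, peak + 99), rule = 2)$y
}

#' Simulate per-gene ground truth
#'
#' Draws gene classes (largest-remainder apportionment of
#' `class_fractions`), maternal abundances (lognormal, normalized so the egg
#' transcriptome totals 1e6 abundance units, i.e. abundances are expected egg
#' TPM), per-class onset times, poly(A)-tail trajectories, zygotic
#' amplitudes, gene structure (exon/intron layout, scaffold placement with
#' histone-like genes clustered on one scaffold), codon-bias groups and
#' miRNA/target assignments, then evaluates expected abundance, tail-length
#' and intron-signal trajectories for the untreated and
#' transcription-inhibited conditions.
#'
#' Class semantics: `stable_maternal` constant; `readenylated` constant
#' abundance with tail lengthening; `deadenylated_only` constant abundance
#' with a sharp tail drop; `deadenylated_then_degraded` tail drop at 2-3
#' h.p.f. then transcription-dependent decay from `decay_onset`;
#' `reactivated_maternal` maternal pool plus zygotic production that is
#' mostly intronic signal; `de_novo_zygotic` no maternal contribution,
#' zygotic onset per `denovo_onset`; `histone_like` non-adenylated, early
#' burst to `histone_share` of the transcriptome; `mirna_target` maternal,
#' decayed from `decay_onset` by a zygotically encoded miRNA (so decay is
#' transcription-dependent).
#'
#' @param config a [simulation_config()].
#' @return object of class `sim_truth`: list with `genes` (per-gene
#'   parameters and labels), `A`/`A_trip` (expected abundance, genes x
#'   timepoints, untreated / triptolide), `L` (tail length nt), `I`/`I_trip`
#'   (intronic signal), and `config`.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  cfg <- config
  tps <- cfg$timepoints
  n <- cfg$n_genes
  with_stream(cfg$seed, 0, {
    counts_per_class <- apportion(n, cfg$class_fractions[sim_classes])
    cls <- rep(sim_classes, counts_per_class)
    cls <- sample(cls)   # interleave classes across gene ids
    gene_id <- sprintf("g%05d", seq_len(n))

    maternal <- cls != "de_novo_zygotic"
    A0 <- numeric(n)
    A0[maternal] <- rlnorm(sum(maternal), meanlog = 0,
                           sdlog = cfg$maternal_sdlog)
    hist_idx <- cls == "histone_like"
    # egg transcriptome totals 1e6 units with the histone-like class at 1.8%;
    # every other maternal class carries egg mass proportional to its gene
    # count, so the compositional drift of the libraries is a property of the
    # configuration, not of the lognormal draws
    hist_frac0 <- if (any(hist_idx)) 0.018 else 0
    if (any(hist_idx))
      A0[hist_idx] <- A0[hist_idx] / sum(A0[hist_idx]) * hist_frac0 * 1e6
    mat_cls <- setdiff(unique(cls[maternal & !hist_idx]), character(0))
    n_mat <- sum(maternal & !hist_idx)
    for (cc in mat_cls) {
      i <- cls == cc & maternal & !hist_idx
      A0[i] <- A0[i] / sum(A0[i]) * (sum(i) / n_mat) * (1 - hist_frac0) * 1e6
    }

    mean_maternal <- if (any(maternal)) mean(A0[maternal]) else 100
    zyg_amp <- numeric(n)
    dn <- cls == "de_novo_zygotic"
    zyg_amp[dn] <- rlnorm(sum(dn),
                          meanlog = log(cfg$zygotic_amp_scale *
                                          mean_maternal) -
                            cfg$zygotic_sdlog^2 / 2,
                          sdlog = cfg$zygotic_sdlog)

    pick <- function(idx, from) {
      out <- rep(NA_real_, n)
      out[idx] <- from[sample.int(length(from), sum(idx), replace = TRUE)]
      out
    }
    t_on <- pick(dn, cfg$denovo_onset)
    t_on[cls == "reactivated_maternal"] <-
      pick(cls == "reactivated_maternal", cfg$reactivation_onset)[
        cls == "reactivated_maternal"]
    t_on[hist_idx] <- 2
    deaden <- pick(cls == "deadenylated_only", cfg$deaden_onset)
    dtd <- cls == "deadenylated_then_degraded"
    deaden[dtd] <- pick(dtd, c(2, 3))[dtd]
    t_decay <- pick(dtd | cls == "mirna_target", cfg$decay_onset)
    readen <- pick(cls == "readenylated", cfg$readen_onset)

    # gene structure
    n_exons <- sample(1:6, n, replace = TRUE,
                      prob = c(0.15, 0.2, 0.2, 0.2, 0.15, 0.1))
    n_exons[hist_idx] <- 1L    # replication-dependent histones are intronless
    # re-activated maternal genes are the class whose zygotic signal is
    # intronic by definition; give them introns
    re_idx <- cls == "reactivated_maternal"
    n_exons[re_idx] <- pmax(n_exons[re_idx], 2L)
    cds_len <- 3L * sample(100:400, n, replace = TRUE)
    utr3_len <- sample(10:300, n, replace = TRUE)
    host <- rep(FALSE, n)
    dn_idx <- which(dn)
    n_mir <- min(cfg$n_mirna, length(dn_idx))
    if (n_mir > 0) host[sample(dn_idx, n_mir)] <- TRUE
    hairpin_len <- 2L * cfg$mirna_len + cfg$hairpin_loop_len
    utr3_len[host] <- pmax(utr3_len[host], hairpin_len + 60L)
    tgt <- cls == "mirna_target"
    utr3_len[tgt] <- pmax(utr3_len[tgt], cfg$mirna_len + 60L)
    mirna_ids <- if (n_mir > 0) sprintf("miR-%s", LETTERS[seq_len(n_mir)])
                 else character(0)
    mirna_id <- rep(NA_character_, n)
    mirna_id[host] <- mirna_ids
    partner <- rep(NA_character_, n)
    if (n_mir > 0 && any(tgt))
      partner[tgt] <- rep_len(mirna_ids, sum(tgt))
    # decoy sites (heavily mismatched) go into stable maternal 3'UTRs
    decoy <- rep(FALSE, n)
    stab_idx <- which(cls == "stable_maternal")
    if (n_mir > 0 && length(stab_idx)) {
      dec_idx <- stab_idx[seq_len(min(n_mir, length(stab_idx)))]
      decoy[dec_idx] <- TRUE
      partner[dec_idx] <- rep_len(mirna_ids, length(dec_idx))
      utr3_len[dec_idx] <- pmax(utr3_len[dec_idx], cfg$mirna_len + 60L)
    }
    tx_len <- 50L + cds_len + utr3_len
    intron_total <- integer(n)
    multi <- n_exons > 1L
    intron_total[multi] <- vapply(which(multi), function(i)
      sum(sample(200:2000, n_exons[i] - 1L, replace = TRUE)), integer(1))

    # scaffold placement: histone cluster on its own scaffold
    scaffold <- character(n)
    ord <- which(!hist_idx)
    scaffold[ord] <- sprintf("HyS%04d",
                             ((seq_along(ord) - 1L) %/%
                                cfg$genes_per_scaffold) + 1L)
    scaffold[hist_idx] <- "HyShist"
    gene_start <- integer(n)
    for (sc in unique(scaffold)) {
      i <- which(scaffold == sc)
      glen <- tx_len[i] + intron_total[i]
      gene_start[i] <- cumsum(c(0L, head(glen + 1000L, -1L))) + 1L
    }
    codon_group <- sample(c("high_bias", "low_bias"), n, replace = TRUE)

    genes <- data.frame(
      gene_id = gene_id, class = cls, A0 = A0, zyg_amp = zyg_amp,
      t_on = t_on, t_decay = t_decay, deaden_onset = deaden,
      readen_onset = readen, n_exons = n_exons, cds_len = cds_len,
      utr3_len = utr3_len, tx_len = tx_len, intron_bp = intron_total,
      scaffold = scaffold, gene_start = gene_start,
      codon_group = codon_group, is_mirna_host = host, mirna_id = mirna_id,
      is_mirna_target = tgt, partner_mirna = partner, is_decoy = decoy,
      stringsAsFactors = FALSE)

    truth <- build_trajectories(genes, cfg)
    truth
  })
}

# expected abundance / tail / intron trajectories; deterministic given genes
build_trajectories <- function(genes, cfg) {
  tps <- cfg$timepoints
  n <- nrow(genes)
  nt <- length(tps)
  tmat <- matrix(rep(tps, each = n), n, nt)
  cls <- genes$class

  ramp_on <- zyg_ramp(tmat, genes$t_on)
  decay_exp <- ifelse(!is.na(genes$t_decay) & tmat >= genes$t_decay,
                      cfg$decay_rate * (tmat - genes$t_decay + 1), 0)
  decay_mult <- pmax(2^(-decay_exp), 0.02)

  A <- matrix(genes$A0, n, nt)
  A[cls == "de_novo_zygotic", ] <-
    (genes$zyg_amp * ramp_on)[cls == "de_novo_zygotic", ]
  re <- cls == "reactivated_maternal"
  A[re, ] <- (genes$A0 * (1 + cfg$reactivated_exon_boost * ramp_on))[re, ]
  dec <- cls %in% c("deadenylated_then_degraded", "mirna_target")
  A[dec, ] <- (genes$A0 * decay_mult)[dec, ]

  # histone burst calibrated so the class hits histone_share at the peak time
  hist_idx <- cls == "histone_like"
  hr <- histone_ramp(tps, cfg$histone_peak_time)
  if (any(hist_idx)) {
    ipeak <- which.min(abs(tps - cfg$histone_peak_time))
    s_non <- sum(A[!hist_idx, ipeak])
    h_total <- max(cfg$histone_share / (1 - cfg$histone_share) * s_non -
                     sum(genes$A0[hist_idx]), 0)
    w <- genes$A0[hist_idx] / sum(genes$A0[hist_idx])
    H <- h_total * w
    A[hist_idx, ] <- genes$A0[hist_idx] +
      H * matrix(rep(hr, each = sum(hist_idx)), sum(hist_idx), nt)
  }

  # triptolide: zygotic production off; transcription-dependent (late) decay
  # off; maternal deadenylation unaffected
  A_trip <- matrix(genes$A0, n, nt)
  early_dec <- dec & !is.na(genes$t_decay) & genes$t_decay < 5
  A_trip[early_dec, ] <- (genes$A0 * decay_mult)[early_dec, ]
  if (cfg$triptolide_null) A_trip <- A

  # poly(A) tails
  L <- matrix(cfg$tail_long, n, nt)
  rd <- cls == "readenylated"
  L[rd, ] <- (cfg$tail_egg_readenylated +
                (cfg$tail_long - cfg$tail_egg_readenylated) *
                zyg_ramp(tmat, genes$readen_onset))[rd, ]
  da <- !is.na(genes$deaden_onset)
  L[da & tmat >= genes$deaden_onset] <- cfg$tail_short
  L[hist_idx, ] <- 0

  # intronic (nascent) signal; intronless genes have none
  zyg_part <- A - matrix(genes$A0, n, nt)
  zyg_part[zyg_part < 0] <- 0
  I <- cfg$intron_background * A + cfg$nascent_intron_fraction * zyg_part
  I[re, ] <- (cfg$intron_background * genes$A0)[re] +
    (genes$A0 * cfg$reactivated_intron_boost * ramp_on)[re, ]
  I_trip <- cfg$intron_background * A_trip
  if (cfg$triptolide_null) I_trip <- I
  I[genes$intron_bp == 0, ] <- 0
  I_trip[genes$intron_bp == 0, ] <- 0

  dimnames(A) <- dimnames(A_trip) <- dimnames(L) <- dimnames(I) <-
    dimnames(I_trip) <- list(genes$gene_id, as.character(tps))
  structure(list(genes = genes, A = A, A_trip = A_trip, L = L, I = I,
                 I_trip = I_trip, config = cfg),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d genes, %d timepoints\n",
              nrow(x$genes), ncol(x$A)))
  print(table(x$genes$class))
  invisible(x)
}

sample_grid <- function(cfg) {
  tps <- cfg$timepoints
  tmax <- tps[length(tps)]
  grid <- expand.grid(replicate = seq_len(cfg$replicates), timepoint_hpf = tps,
                      condition = "untreated", protocol = c("polyA", "ribo"),
                      stringsAsFactors = FALSE)
  treat <- expand.grid(replicate = seq_len(cfg$replicates),
                       timepoint_hpf = tmax,
                       condition = c("dmso", "triptolide"),
                       protocol = c("polyA", "ribo"),
                       stringsAsFactors = FALSE)
  meta <- rbind(grid, treat)
  meta$sample_id <- sprintf("%s_t%s_%s_r%d", meta$protocol,
                            gsub("\\.", "p", meta$timepoint_hpf),
                            meta$condition, meta$replicate)
  meta[, c("sample_id", "timepoint_hpf", "protocol", "condition",
           "replicate")]
}

draw_counts <- function(mu, alpha) {
  if (alpha < 1e-12) rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = 1 / alpha)
}

#' Simulate count matrices from a ground truth
#'
#' Draws the four count tables of the study design. Expected rRNA-depleted
#' counts are proportional to abundance times transcript length; expected
#' poly(A)+ counts additionally carry the tail-capture probability; each
#' library is scaled to `library_depth` expected reads (compositional, as in
#' sequencing). Gene-level quantification of an rRNA-depleted library is
#' exonic, so the exon table re-uses the rRNA-depleted draws for those
#' samples and the pre-mRNA table adds independently drawn intronic reads;
#' `exon <= premRNA` therefore holds exactly. Counts for each matrix come
#' from a dedicated random stream derived from the master seed, so matrices
#' do not perturb each other.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the matching [simulation_config()]; defaults to the one
#'   stored in `truth`.
#' @return list with `polyA`, `ribo`, `exon`, `premrna` ([count_matrix()]
#'   objects; `exon`/`premrna` cover the rRNA-depleted samples) and `meta`.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  cfg <- config
  if (cfg$library_depth <= 0) stopf("library_depth must be positive")
  genes <- truth$genes
  tps <- cfg$timepoints
  meta <- sample_grid(cfg)
  tcol <- function(t) match(as.character(t), colnames(truth$A))

  expected <- function(protocol, condition, t) {
    j <- tcol(t)
    A <- if (condition == "triptolide") truth$A_trip[, j] else truth$A[, j]
    w <- A * genes$tx_len / 1e3
    if (protocol == "polyA")
      w <- w * capture_probability(truth$L[, j], cfg$tail_capture_K,
                                   cfg$tail_capture_h)
    w
  }

  mats <- list()
  for (prot in c("polyA", "ribo")) {
    pm <- meta[meta$protocol == prot, , drop = FALSE]
    cm <- with_stream(cfg$seed, if (prot == "polyA") 1 else 2, {
      m <- matrix(0L, nrow(genes), nrow(pm),
                  dimnames = list(genes$gene_id, pm$sample_id))
      for (s in seq_len(nrow(pm))) {
        w <- expected(prot, pm$condition[s], pm$timepoint_hpf[s])
        tot <- sum(w)
        mu <- if (tot > 0) cfg$library_depth * w / tot else w * 0
        m[, s] <- draw_counts(mu, cfg$nb_dispersion)
      }
      m
    })
    mats[[prot]] <- count_matrix(cm, pm)
  }

  # intronic reads for the rRNA-depleted libraries
  rm_ <- meta[meta$protocol == "ribo", , drop = FALSE]
  intr <- with_stream(cfg$seed, 3, {
    m <- matrix(0L, nrow(genes), nrow(rm_),
                dimnames = list(genes$gene_id, rm_$sample_id))
    for (s in seq_len(nrow(rm_))) {
      j <- tcol(rm_$timepoint_hpf[s])
      I <- if (rm_$condition[s] == "triptolide") truth$I_trip[, j]
           else truth$I[, j]
      w_ex <- expected("ribo", rm_$condition[s], rm_$timepoint_hpf[s])
      w_in <- I * genes$intron_bp / 1e3
      tot <- sum(w_ex)
      mu <- if (tot > 0) cfg$library_depth * w_in / tot else w_in * 0
      m[, s] <- draw_counts(mu, cfg$nb_dispersion)
    }
    m
  })
  exon <- mats$ribo
  premrna <- count_matrix(exon$counts + intr, rm_)
  list(polyA = mats$polyA, ribo = mats$ribo, exon = exon, premrna = premrna,
       meta = meta)
}

#' Exon intervals implied by a simulated truth
#'
#' Lays the transcript length of each gene onto its scaffold as `n_exons`
#' exons separated by the gene's introns; suitable for [write_gtf()] /
#' [gene_models()].
#'
#' @param truth a [simulate_truth()] result.
#' @return exon data.frame (1-based inclusive coordinates).
#' @export
truth_exons <- function(truth) {
  g <- truth$genes
  with_stream(truth$config$seed, 5, {
    rows <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      ne <- g$n_exons[i]
      # split transcript length into ne exon pieces, introns into ne-1 gaps
      cuts <- if (ne > 1)
        sort(sample(seq_len(g$tx_len[i] - 1), ne - 1)) else integer(0)
      ex_len <- diff(c(0, cuts, g$tx_len[i]))
      in_len <- if (ne > 1) {
        p <- diff(sort(c(0, runif(ne - 2), 1)))
        pmax(round(p * g$intron_bp[i]), 1)
      } else integer(0)
      start <- g$gene_start[i] +
        cumsum(c(0, head(ex_len, -1) + in_len))
      rows[[i]] <- data.frame(
        gene_id = g$gene_id[i], scaffold = g$scaffold[i], strand = "+",
        start = start, end = start + ex_len - 1L,
        transcript_id = paste0(g$gene_id[i], ".t1"))
    }
    do.call(rbind, rows)
  })
}

#' Run the full forward simulation
#'
#' Convenience wrapper: truth, counts, gene models and sequences in one call.
#'
#' @param config a [simulation_config()].
#' @return list with `truth`, `counts` (see [simulate_counts()]), `exons`,
#'   `models` ([gene_models()]) and `seqs` (see [simulate_sequences()]).
#' @export
simulate_mzt <- function(config = simulation_config()) {
  truth <- simulate_truth(config)
  counts <- simulate_counts(truth, config)
  exons <- truth_exons(truth)
  seqs <- simulate_sequences(truth, config)
  list(truth = truth, counts = counts, exons = exons,
       models = gene_models(exons), seqs = seqs)
}
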