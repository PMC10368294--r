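# Expression-level statistics: TPM, size factors, the negative-binomial
# differential test used throughout the pipeline, and the small tests
# (Benjamini-Hochberg, Wilcoxon signed-rank, Pearson chi-squared) the
# downstream stages rely on.

#' Transcripts per million
#'
#' `TPM_g = 1e6 * (c_g / l_g) / sum_j (c_j / l_j)`, so each sample column
#' sums to one million over genes with a defined length.
#'
#' @param counts a [count_matrix()] or plain genes x samples matrix.
#' @param lengths named numeric vector of effective gene lengths in bp,
#'   covering every gene in `counts`; all lengths must be positive.
#' @return genes x samples numeric matrix of TPM values.
#' @export
compute_tpm <- function(counts, lengths) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(m))
      stopf("lengths must be named or match the number of genes")
    names(lengths) <- rownames(m)
  }
  miss <- setdiff(rownames(m), names(lengths))
  if (length(miss)) stopf("no length for %d gene(s), e.g. %s",
                          length(miss), miss[1])
  l <- lengths[rownames(m)]
  if (any(!is.finite(l)) || any(l <= 0)) stopf("gene lengths must be > 0")
  rate <- m / l
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warnf("%d zero-depth sample(s) yield all-zero TPM columns", sum(zero))
    denom[zero] <- 1
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median across genes
#' of the ratio of its count to the gene's geometric mean over samples, using
#' only genes with non-zero counts in every sample. Factors are rescaled to
#' have geometric mean 1.
#'
#' @param counts a [count_matrix()] or genes x samples matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (ncol(m) == 1L) return(setNames(1, colnames(m)))
  ok <- rowSums(m == 0) == 0
  if (!any(ok))
    stopf(paste("no gene has non-zero counts in all samples;",
                "supply a pseudo-reference or prefilter samples"))
  lg <- log(m[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(exp(lg - ref), 2, median)
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1, returned in the input
#' order.
#'
#' @param pvalues numeric vector in `[0, 1]` (no `NA`).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1] with no NA")
  n <- length(pvalues)
  if (n <= 1L) return(pvalues)
  o <- order(pvalues)
  q <- pmin(1, rev(cummin(rev(pvalues[o] * n / seq_len(n)))))
  q[order(o)]
}

# log NB likelihood of raw counts `raw` (genes x samples) with per-sample
# size factors `sf` and per-gene normalized means `q`: count_gs ~
# NB(sf_s * q_g, alpha_g); alpha may be scalar or per-gene; alpha = 0
# degenerates to Poisson
nb_loglik <- function(raw, q, sf, alpha) {
  mu <- pmax(outer(q, sf), 1e-8)
  alpha <- rep_len(alpha, nrow(raw))
  out <- numeric(nrow(raw))
  pois <- alpha < 1e-7
  if (any(pois)) {
    kp <- raw[pois, , drop = FALSE]
    out[pois] <- rowSums(matrix(dpois(kp, mu[pois, ], log = TRUE),
                                nrow = nrow(kp)))
  }
  if (any(!pois)) {
    kn <- raw[!pois, , drop = FALSE]
    out[!pois] <- rowSums(matrix(
      dnbinom(kn, size = rep(1 / alpha[!pois], ncol(raw)),
              mu = mu[!pois, , drop = FALSE], log = TRUE), nrow = nrow(kn)))
  }
  out
}

# Cox-Reid adjusted profile log-likelihood for a common dispersion under the
# two-group means model; the adjustment 0.5*log(sum_i w_i) per gene/group
# (w = mu/(1+alpha*mu)) compensates the plug-in of estimated group means.
cr_profile <- function(alpha, rawA, rawB, qA, qB, sfA, sfB) {
  qA <- pmax(qA, 1e-8)
  qB <- pmax(qB, 1e-8)
  wsum <- function(q, sf) {
    mu <- outer(q, sf)
    rowSums(mu / (1 + alpha * mu))
  }
  adj <- 0.5 * (log(wsum(qA, sfA)) + log(wsum(qB, sfB)))
  sum(nb_loglik(rawA, qA, sfA, alpha) + nb_loglik(rawB, qB, sfB, alpha) -
        adj)
}

# per-gene method-of-moments dispersion, pooled across the two groups and
# shrunk toward the common value with prior_df pseudo-degrees of freedom
moment_dispersion <- function(kA, kB, common, prior_df = 10) {
  mom <- function(k) {
    if (ncol(k) < 2L) return(rep(NA_real_, nrow(k)))
    m <- rowMeans(k)
    v <- apply(k, 1, var)
    (v - m) / pmax(m, 1e-8)^2
  }
  dfA <- max(ncol(kA) - 1L, 0L)
  dfB <- max(ncol(kB) - 1L, 0L)
  d <- dfA + dfB
  if (d == 0L) return(rep(common, nrow(kA)))
  ag <- (dfA * ifelse(is.na(mom(kA)), 0, mom(kA)) +
           dfB * ifelse(is.na(mom(kB)), 0, mom(kB))) / d
  pmax((d * ag + prior_df * common) / (d + prior_df), 0)
}

#' Negative-binomial differential expression test
#'
#' A self-contained stand-in for a DESeq2-style two-group contrast. Genes
#' with fewer than `min_total` reads summed over the tested samples are
#' flagged `filtered` and carry no p-value. Remaining genes are tested on
#' median-of-ratios normalized counts with a negative-binomial likelihood
#' ratio test (group means vs a common mean) against chi-squared with one
#' degree of freedom. The NB dispersion is, by default, a single common value
#' maximizing the Cox-Reid adjusted profile likelihood across all tested
#' genes; `dispersion = "moment"` shrinks per-gene method-of-moments
#' estimates toward that common value, and when both groups have a single
#' sample the configured `prior_dispersion` is used. BH adjustment is
#' performed over tested genes only.
#'
#' @param counts a [count_matrix()] or genes x samples integer matrix.
#' @param groupA,groupB disjoint character vectors of sample ids (or column
#'   indices) for the reference and contrast group; `log2FoldChange` is B
#'   over A.
#' @param min_total prefilter: minimum total reads across the tested samples.
#' @param dispersion `"common"` (default), `"moment"`, or a single numeric
#'   dispersion to use as-is.
#' @param prior_dispersion dispersion used when no replicates are available.
#' @param prior_df prior weight (pseudo-df) for `"moment"` shrinkage.
#' @return data.frame with columns `gene_id`, `baseMean`, `log2FoldChange`,
#'   `pvalue`, `padj`, `filtered`; attributes `protocol` (when unambiguous
#'   from metadata) and `dispersion`.
#' @export
nb_test <- function(counts, groupA, groupB, min_total = 10,
                    dispersion = "common", prior_dispersion = 0.1,
                    prior_df = 10) {
  meta <- NULL
  m <- counts
  if (inherits(counts, "count_matrix")) {
    meta <- counts$meta
    m <- counts$counts
  }
  idx <- function(g) {
    if (is.character(g)) {
      bad <- setdiff(g, colnames(m))
      if (length(bad)) stopf("unknown sample id(s): %s",
                             paste(bad, collapse = ", "))
      match(g, colnames(m))
    } else as.integer(g)
  }
  iA <- idx(groupA)
  iB <- idx(groupB)
  if (!length(iA) || !length(iB)) stopf("both groups must be non-empty")
  if (length(intersect(iA, iB))) stopf("groups must be disjoint")
  sel <- m[, c(iA, iB), drop = FALSE]
  tot <- rowSums(sel)
  filtered <- tot < min_total
  sf <- size_factors(sel)
  k <- sweep(sel, 2, sf, "/")
  nA <- length(iA)
  nB <- length(iB)
  kA <- k[, seq_len(nA), drop = FALSE]
  kB <- k[, nA + seq_len(nB), drop = FALSE]
  muA <- rowMeans(kA)
  muB <- rowMeans(kB)
  baseMean <- rowMeans(k)
  muAf <- pmax(muA, 0.5)
  muBf <- pmax(muB, 0.5)
  lfc <- log2(muBf / muAf)

  test <- which(!filtered)
  pv <- rep(NA_real_, nrow(sel))
  if (length(test)) {
    sfA <- sf[seq_len(nA)]
    sfB <- sf[nA + seq_len(nB)]
    rawA <- sel[test, seq_len(nA), drop = FALSE]
    rawB <- sel[test, nA + seq_len(nB), drop = FALSE]
    tA <- kA[test, , drop = FALSE]
    tB <- kB[test, , drop = FALSE]
    if (is.numeric(dispersion)) {
      a_use <- rep(dispersion, length(test))
      a_common <- dispersion
    } else if (nA == 1L && nB == 1L) {
      a_use <- rep(prior_dispersion, length(test))
      a_common <- prior_dispersion
    } else {
      opt <- optimize(function(la)
        cr_profile(exp(la), rawA, rawB, muA[test], muB[test], sfA, sfB),
        interval = c(log(1e-6), log(10)), maximum = TRUE, tol = 1e-4)
      a_common <- exp(opt$maximum)
      if (a_common < 2e-6) a_common <- 0
      a_use <- switch(match.arg(dispersion, c("common", "moment")),
                      common = rep(a_common, length(test)),
                      moment = moment_dispersion(tA, tB, a_common, prior_df))
    }
    a_use <- pmax(a_use, 1e-8)
    mu0 <- rowMeans(k[test, , drop = FALSE])
    ll1 <- nb_loglik(rawA, muA[test], sfA, a_use) +
      nb_loglik(rawB, muB[test], sfB, a_use)
    ll0 <- nb_loglik(sel[test, , drop = FALSE], mu0, sf, a_use)
    lrt <- pmax(2 * (ll1 - ll0), 0)
    pv[test] <- pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  padj <- rep(NA_real_, nrow(sel))
  if (length(test)) padj[test] <- bh_adjust(pv[test])
  res <- data.frame(gene_id = rownames(sel), baseMean = baseMean,
                    log2FoldChange = ifelse(filtered, NA_real_, lfc),
                    pvalue = pv, padj = padj, filtered = filtered,
                    row.names = NULL)
  if (!is.null(meta)) {
    prot <- unique(meta$protocol[c(iA, iB)])
    if (length(prot) == 1L) attr(res, "protocol") <- prot
  }
  attr(res, "dispersion") <- if (length(test)) a_common else NA_real_
  attr(res, "n_A") <- nA
  attr(res, "n_B") <- nB
  class(res) <- c("mzt_de", "data.frame")
  res
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on paired differences. Exact
#' p-values are computed by enumerating the sign-flip distribution (via its
#' generating function over the mid-rank support) for up to `exact_max`
#' non-zero differences; larger samples use the normal approximation with
#' mid-rank tie correction and a continuity correction. Zero differences are
#' dropped first.
#'
#' @param paired_diffs numeric vector of paired differences.
#' @param exact_max enumerate exactly up to this many non-zero differences.
#' @return list with `statistic` (W+, sum of ranks of positive differences),
#'   `p.value`, `n` (non-zero differences) and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_diffs, exact_max = 25) {
  d <- paired_diffs[paired_diffs != 0]
  if (anyNA(paired_diffs)) stopf("differences must not contain NA")
  if (!length(d)) stopf("degenerate paired sample: all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n <- length(d)
  if (n <= exact_max) {
    # distribution of W+ over 2^n sign assignments, on the doubled-rank
    # integer grid so mid-ranks (x.5) stay exact
    r2 <- as.integer(round(2 * r))
    dist <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2)) / 2   # mid-ranks make this tie-corrected
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p.value = p, n = n, method = method)
}

#' Pearson chi-squared test of independence for a 2 x k table
#'
#' @param table integer matrix with 2 rows; all row and column sums must be
#'   positive and no expected cell may be zero (pool categories upstream).
#' @return list with `statistic`, `dof` (`k - 1`) and `p.value`.
#' @export
chi2_independence <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2L) stopf("table must have exactly 2 rows")
  if (any(tab < 0)) stopf("table entries must be non-negative")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs <= 0) || any(cs <= 0))
    stopf("all row and column sums must be positive")
  expected <- outer(rs, cs) / sum(tab)
  if (any(expected == 0)) stopf("zero expected cell; pool categories first")
  stat <- sum((tab - expected)^2 / expected)
  dof <- ncol(tab) - 1L
  list(statistic = stat, dof = dof,
       p.value = pchisq(stat, df = dof, lower.tail = FALSE))
}

#' @export
print.mzt_de <- function(x, ...) {
  cat(sprintf("NB differential test: %d genes (%d filtered), n = %d vs %d%s\n",
              nrow(x), sum(x$filtered), attr(x, "n_A"), attr(x, "n_B"),
              if (!is.null(attr(x, "protocol")))
                paste0(", protocol ", attr(x, "protocol")) else ""))
  print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}
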