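# Independent oracles used to validate the package's own implementations.
# These are deliberately naive (literal definitions, exhaustive enumeration)
# and are never called by package code.

# literal Benjamini-Hochberg step-up, double loop over the definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    vals <- sapply(i:n, function(j) p[o[j]] * n / j)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
brute_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive maximum base pairing (no pseudoknots, min loop) by recursion
brute_max_pairs <- function(seq, allow_gu = TRUE, min_loop = 3) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  ok <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AU", "UA", "GC", "CG") ||
      (allow_gu && p %in% c("GU", "UG"))
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (ok(s[i], s[k])) {
        inner <- if (k - 1 >= i + 1) rec(i + 1, k - 1) else 0L
        right <- if (k + 1 <= j) rec(k + 1, j) else 0L
        best <- max(best, 1L + inner + right)
      }
    }
    best
  }
  if (length(s) < 2) 0L else rec(1L, length(s))
}

# small count_matrix fixture: two groups of `n` samples, NB counts
make_two_group_cm <- function(mu, n = 3, alpha = 0.1, fold = 1, seed = 1,
                              protocol = "ribo") {
  set.seed(seed)
  ngene <- length(mu)
  draw <- function(m) {
    if (alpha == 0) rpois(ngene, m) else rnbinom(ngene, mu = m, size = 1 / alpha)
  }
  counts <- cbind(
    sapply(seq_len(n), function(i) draw(mu)),
    sapply(seq_len(n), function(i) draw(mu * fold)))
  rownames(counts) <- sprintf("g%04d", seq_len(ngene))
  colnames(counts) <- c(sprintf("A%d", seq_len(n)), sprintf("B%d", seq_len(n)))
  meta <- data.frame(sample_id = colnames(counts),
                     timepoint_hpf = rep(c(0, 7), each = n),
                     protocol = protocol, condition = "untreated",
                     replicate = rep(seq_len(n), 2))
  count_matrix(counts, meta)
}
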