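# Expression core: TPM, size factors, the NB test, BH, Wilcoxon, chi-squared.

test_that("TPM matches its closed form and normalizes columns", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(m, c(a = 1000, b = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3))
  expect_equal(sum(tpm), 1e6)

  single <- matrix(7, 1, 1, dimnames = list("a", "s1"))
  expect_equal(unname(compute_tpm(single, c(a = 500))[1, 1]), 1e6)

  zero <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(tz <- compute_tpm(zero, c(a = 100, b = 100)), "zero-depth")
  expect_true(all(tz == 0))

  set.seed(1)
  big <- matrix(rpois(600, 50), 100, 6,
                dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:6)))
  tb <- compute_tpm(big, setNames(runif(100, 200, 3000),
                                  sprintf("g%d", 1:100)))
  expect_equal(unname(colSums(tb)), rep(1e6, 6), tolerance = 1e-9)

  expect_error(compute_tpm(big, setNames(rep(0, 100), sprintf("g%d", 1:100))),
               "lengths must be > 0")
})

test_that("size factors are median-of-ratios with geometric-mean scaling", {
  m <- matrix(rpois(200, 100), 100, 2,
              dimnames = list(sprintf("g%d", 1:100), c("s1", "s2")))
  m[, 2] <- m[, 1]
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = m[, 1], s2 = m[, 1] * 2L)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)

  allzero <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(allzero), "pseudo-reference")
})

test_that("BH adjustment equals the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:50, 1)
    p <- round(runif(n), 3)   # rounding forces ties
    expect_equal(bh_adjust(p), brute_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
})

test_that("exact Wilcoxon signed-rank matches full enumeration", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p.value, 0.25)

  expect_equal(wilcoxon_signed_rank(c(-1, 1))$p.value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "degenerate")

  set.seed(7)
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n, sd = 2), if (rep %% 2) 3 else 0)  # some tied |d|
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p.value, brute_wilcoxon(d),
                 tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximation agrees with stats::wilcox.test", {
  set.seed(11)
  d <- rnorm(1000, mean = 0.05)
  ours <- wilcoxon_signed_rank(d)
  ref <- wilcox.test(d, correct = TRUE, exact = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  # and the normal path stays close to exact enumeration at moderate n
  set.seed(12)
  d2 <- rnorm(12, 0.5)
  exact <- wilcoxon_signed_rank(d2)$p.value
  approx <- wilcoxon_signed_rank(d2, exact_max = 5)$p.value
  expect_lt(abs(exact - approx), 0.05)
})

test_that("chi-squared independence matches the Pearson form", {
  r0 <- chi2_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  r <- chi2_independence(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$statistic, 20 / 3)
  expect_equal(r$dof, 1)
  ref <- suppressWarnings(chisq.test(matrix(c(20, 10, 10, 20), 2),
                                     correct = FALSE))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p.value, ref$p.value)

  u <- matrix(rep(c(10, 30), 5), nrow = 2)
  expect_equal(chi2_independence(u)$dof, 4)

  expect_error(chi2_independence(matrix(c(0, 0, 5, 5), 2)), "positive")
  expect_error(chi2_independence(matrix(1:9, 3)), "2 rows")
})

test_that("nb_test prefilters, detects large effects, and validates groups", {
  cm <- make_two_group_cm(mu = c(rep(100, 50), 2), n = 3, alpha = 0.05,
                          seed = 3)
  # the last gene has ~4 reads per group pair; force it under the filter
  cm$counts[51, ] <- c(1L, 0L, 1L, 0L, 1L, 1L)
  de <- nb_test(cm, paste0("A", 1:3), paste0("B", 1:3), min_total = 10)
  expect_true(de$filtered[51])
  expect_true(is.na(de$pvalue[51]) && is.na(de$padj[51]))
  expect_identical(attr(de, "protocol"), "ribo")

  expect_error(nb_test(cm, c("A1", "A2"), c("A2", "B1")), "disjoint")
  expect_error(nb_test(cm, character(0), "B1"), "non-empty")

  # 100-fold effect at n = 3 is always found
  set.seed(5)
  mu <- rep(10, 100)
  cm2 <- make_two_group_cm(mu, n = 3, alpha = 0.05, seed = 5)
  cm2$counts[1:10, 4:6] <- matrix(rnbinom(30, mu = 1000, size = 20), 10)
  de2 <- nb_test(cm2, paste0("A", 1:3), paste0("B", 1:3))
  expect_true(all(de2$padj[1:10] < 1e-6))
  expect_true(all(de2$log2FoldChange[1:10] > 5))
})

test_that("nb_test with single samples falls back to the prior dispersion", {
  cm <- make_two_group_cm(mu = rep(100, 40), n = 1, alpha = 0.1, seed = 9)
  de <- nb_test(cm, "A1", "B1", prior_dispersion = 0.1)
  expect_equal(attr(de, "dispersion"), 0.1)
  expect_true(all(de$padj[!de$filtered] >= 0 & de$padj[!de$filtered] <= 1))
})
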