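test_that("Friedman test: degenerate and closed-form cases", {
  # identical treatments in every block: no effect, p = 1
  m <- matrix(c(2, 5, 9), nrow = 3, ncol = 3)
  r0 <- friedman_test(m)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  # strictly ordered treatments in every block (3 blocks, 3 treatments):
  # statistic = 12n/(k(k+1)) * sum (Rbar_j - (k+1)/2)^2 = 6
  m1 <- rbind(c(1, 2, 3), c(2, 4, 6), c(0.5, 1.5, 2.5))
  r1 <- friedman_test(m1)
  expect_equal(r1$statistic, 6)
  expect_equal(r1$p.value, stats::pchisq(6, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r1$p.value, 0.0498, tolerance = 1e-3)

  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("Friedman statistic is invariant under monotone transformations", {
  m <- withr::with_seed(5, matrix(stats::rexp(24), nrow = 6))
  expect_equal(friedman_test(m)$statistic,
               friedman_test(log(m + 1))$statistic)
  expect_equal(friedman_test(m)$statistic,
               friedman_test(m^3)$statistic)
})

test_that("Friedman p-value tracks the exact permutation distribution", {
  # exhaustive within-block permutation oracle for small n, k = 3
  exact_p <- function(m) {
    k <- ncol(m)
    perms <- as.matrix(expand.grid(rep(list(1:factorial(k)), nrow(m))))
    allp <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                   ncol = k, byrow = TRUE)
    obs <- friedman_test(m)$statistic
    stats_all <- apply(perms, 1, function(pr) {
      mm <- m
      for (i in seq_len(nrow(m))) mm[i, ] <- m[i, allp[pr[i], ]]
      friedman_test(mm)$statistic
    })
    mean(stats_all >= obs - 1e-9)
  }
  for (s in 1:3) {
    m <- withr::with_seed(s, matrix(stats::rnorm(12, sd = 1) +
                                      rep(c(0, 0.8, 1.6), each = 4), nrow = 4))
    p_chisq <- friedman_test(m)$p.value
    p_perm <- exact_p(m)
    expect_lt(abs(p_chisq - p_perm), 0.06)
  }
})

test_that("signed-rank test reproduces exact small-sample p-values", {
  # six strictly positive differences: two-sided p = 2/2^6
  r <- signed_rank_test(2:7, 1:6)
  expect_equal(r$p.value, 2 / 64)
  expect_equal(r$statistic, 21)
  expect_equal(r$method, "exact")

  # identical vectors: all differences zero, p = 1 (Pratt drops them)
  r0 <- signed_rank_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$p.value, 1)

  # cross-check against base R's exact signed-rank on tie/zero-free data
  for (s in 1:8) {
    xy <- withr::with_seed(s, list(x = stats::rnorm(10), y = stats::rnorm(10)))
    got <- signed_rank_test(xy$x, xy$y)$p.value
    want <- stats::wilcox.test(xy$x, xy$y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Pratt zero handling ranks zeros before dropping them", {
  # with d = (0, 1, 2): Pratt ranks are (1, 2, 3); zeros drop, V = 5 of
  # the attainable {0, 2, 3, 5}; two-sided exact p over 4 sign patterns
  r <- signed_rank_test(c(5, 6, 7), c(5, 5, 5))
  expect_equal(r$n_nonzero, 2L)
  expect_equal(r$statistic, 5)
  expect_equal(r$p.value, 2 * 1 / 4)
})

test_that("Bonferroni adjustment multiplies and caps pairwise p-values", {
  m <- withr::with_seed(9, cbind(A = stats::rnorm(8), B = stats::rnorm(8),
                                 C = stats::rnorm(8) + 3))
  res <- wilcoxon_bonferroni(m)
  expect_equal(nrow(res), 3)
  expect_equal(res$p.adj, pmin(1, 3 * res$p.raw))
  expect_true(all(res$p.adj >= res$p.raw))
  # identical columns: adjusted p = 1, not significant
  m2 <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(2, 3, 4, 5))
  res2 <- wilcoxon_bonferroni(m2)
  ab <- res2[res2$a == "a" & res2$b == "b", ]
  expect_equal(ab$p.adj, 1)
  expect_false(ab$significant)
})

test_that("box statistics use the linear-interpolation quantile rule", {
  b <- box_stats(1:8)
  # type-7 closed form: h = 1 + (n-1)p
  expect_equal(b$median, 4.5)
  expect_equal(b$q1, 2.75)
  expect_equal(b$q3, 6.25)
  expect_equal(b$whisker_low, 2.75 - 1.5 * 3.5)
  expect_equal(b$whisker_high, 6.25 + 1.5 * 3.5)
  expect_false(any(b$outlier))

  cc <- box_stats(rep(7, 5))
  expect_equal(cc$median, 7)
  expect_equal(cc$q1, cc$q3)
  expect_false(any(cc$outlier))

  ov <- box_stats(c(1, 2, 3, 4, 100))
  expect_true(ov$outlier[5])
  expect_false(any(ov$outlier[1:4]))
})
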