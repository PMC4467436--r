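test_that("rank-sum test: exact examples, enumeration oracle, base-R agreement", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.10)
  expect_equal(unname(res$statistic), 0)

  # identical multisets are perfectly symmetric
  expect_equal(wilcoxon_rank_sum(c(1, 2, 5), c(1, 2, 5))$p.value, 1)

  set.seed(1)
  for (i in 1:10) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    mine <- wilcoxon_rank_sum(x, y)
    expect_equal(mine$p.value, oracle_wilcox_p(x, y), tolerance = 1e-12)
    expect_equal(mine$p.value, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large/tied samples use the corrected normal approximation as base R does
  set.seed(2)
  x <- round(rnorm(30), 1); y <- round(rnorm(25, 0.3), 1)
  expect_equal(wilcoxon_rank_sum(x, y)$p.value,
               suppressWarnings(wilcox.test(x, y)$p.value), tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("hypergeometric overlap test: exact values, log space, monotonicity", {
  expect_equal(hypergeom_overlap_test(0, 5, 5, 20), 1)
  expect_equal(hypergeom_overlap_test(3, 5, 5, 20), 1126 / 15504,
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_test(3, 5, 5, 20),
               oracle_hyper_p(3, 5, 5, 20), tolerance = 1e-12)
  expect_equal(hypergeom_overlap_test(60, 500, 400, 1e4),
               phyper(59, 500, 9500, 400, lower.tail = FALSE),
               tolerance = 1e-10)
  # deep tail: finite and correct in log space far below 1e-100
  lp <- hypergeom_overlap_test(300, 674, 674, 10000, log.p = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, log(1e-100))
  expect_equal(lp, phyper(299, 674, 10000 - 674, 674, lower.tail = FALSE,
                          log.p = TRUE), tolerance = 1e-8)
  # monotone decreasing in k at fixed margins
  ps <- vapply(0:10, hypergeom_overlap_test, numeric(1), K = 20, n = 30,
               N = 100)
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_overlap_test(6, 5, 5, 20), "inconsistent")
})

test_that("binomial test: minimum-likelihood two-sided tails", {
  expect_equal(binomial_test(5, 10), 1)
  expect_equal(binomial_test(8, 10), 112 / 1024, tolerance = 1e-12)
  expect_equal(binomial_test(10, 10), 2 / 1024, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:12, 1); k <- sample(0:n, 1)
    p0 <- sample(c(0.2, 0.5, 0.7), 1)
    expect_equal(binomial_test(k, n, p0), oracle_binom_p(k, n, p0),
                 tolerance = 1e-12)
    expect_equal(binomial_test(k, n, p0), binom.test(k, n, p0)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(binomial_test(1, 2, p0 = 1), "strictly inside")
})

test_that("Fisher's exact test: enumeration oracle, odds ratios, zero margins", {
  tab <- matrix(c(10, 10, 10, 10), 2)
  f <- fisher_exact(tab)
  expect_equal(f$p.value, 1)
  expect_equal(f$estimate[["sample_or"]], 1)

  tab2 <- matrix(c(8, 1, 2, 9), 2)
  f2 <- fisher_exact(tab2)
  expect_equal(f2$estimate[["sample_or"]], 36)
  expect_equal(f2$p.value, oracle_fisher_p(tab2), tolerance = 1e-12)

  set.seed(4)
  for (i in 1:12) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    mine <- fisher_exact(tab)
    ref <- fisher.test(tab)
    expect_equal(mine$p.value, oracle_fisher_p(tab), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    if (is.finite(mine$estimate[["cmle_or"]]) &&
        mine$estimate[["cmle_or"]] > 0)
      expect_equal(mine$estimate[["cmle_or"]], unname(ref$estimate),
                   tolerance = 1e-4)
  }
  zero <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(zero$p.value, 1)
  expect_true(is.na(zero$estimate[["sample_or"]]))
})

test_that("Welch t-test matches closed form and handles degenerate variance", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  ref <- t.test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(unname(w$statistic["t"]), unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(w$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(w$statistic["t"]), -1 / sqrt(2 / 3), tolerance = 1e-12)

  same <- welch_t_test(c(1, 5, 9), c(1, 5, 9))
  expect_equal(unname(same$statistic["t"]), 0)
  expect_equal(same$p.value, 1)

  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2))$p.value, 1)
  expect_equal(welch_t_test(c(2, 2, 2), c(3, 3))$p.value, 0)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2 values")
})

test_that("BH adjustment: step-up recursion and properties", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:5) {
    p <- runif(sample(3:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  p_na <- c(0.01, NA, 0.04)
  expect_equal(bh_fdr(p_na), p.adjust(p_na, "BH"), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank-sum and Welch type-I error sit at the nominal level", {
  set.seed(123)
  rej <- replicate(400, {
    x <- rnorm(20); y <- rnorm(20)
    c(wilcoxon_rank_sum(x, y)$p.value <= 0.05,
      welch_t_test(x, y)$p.value <= 0.05)
  })
  expect_gt(mean(rej[1, ]), 0.02); expect_lt(mean(rej[1, ]), 0.08)
  expect_gt(mean(rej[2, ]), 0.02); expect_lt(mean(rej[2, ]), 0.08)
})
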