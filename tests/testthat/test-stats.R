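test_that("signed-rank test handles degenerate and textbook inputs", {
  x <- c(3, 1, 4, 1, 5)
  w <- wilcoxon_signed_rank(x, x)
  expect_true(w$degenerate)
  expect_equal(w$p_value, 1)

  # d = (+1..+5, -6): W- = 6; p = 2 * 14 / 64 by full 64-pattern count
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 0), c(0, 0, 0, 0, 0, 6))
  expect_equal(w$statistic, 6)
  expect_equal(w$p_value, 28 / 64)
  expect_identical(w$method, "exact")
})

test_that("exact signed-rank p matches the sign-pattern oracle up to n = 8", {
  set.seed(101)
  for (n in 3:8) {
    for (rep in 1:8) {
      # draws with heavy ties and occasional zero differences
      x <- sample(1:4, n, replace = TRUE)
      y <- sample(1:4, n, replace = TRUE)
      if (all(x == y)) x[1] <- x[1] + 1
      got <- wilcoxon_signed_rank(x, y)
      expect_equal(got$p_value, oracle_signrank_p(x, y),
                   info = paste("n =", n, "rep =", rep))
    }
  }
})

test_that("signed-rank agrees with base R on tie-free data and across the
          exact/normal crossover", {
  set.seed(102)
  x <- rnorm(15); y <- rnorm(15)
  got <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, ref$p.value)

  # exact and approximate branches agree within 0.01 absolute at n = 25
  for (s in 1:5) {
    set.seed(200 + s)
    x <- rnorm(25); y <- rnorm(25, 0.3)
    p_exact <- wilcoxon_signed_rank(x, y, exact_max_n = 25)$p_value
    p_norm <- wilcoxon_signed_rank(x, y, exact_max_n = 0)$p_value
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("Mann-Whitney handles textbook, degenerate and tied inputs", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 2 / choose(6, 3))

  mw <- mann_whitney(c(1, 2, 2), c(2, 1, 2))
  expect_equal(mw$p_value, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p matches the permutation oracle for all
          group sizes with pooled n <= 8", {
  set.seed(103)
  for (na in 2:4) {
    for (nb in 2:4) {
      for (rep in 1:5) {
        a <- sample(1:5, na, replace = TRUE)
        b <- sample(1:5, nb, replace = TRUE)
        if (length(unique(c(a, b))) == 1L) a[1] <- a[1] + 1
        got <- mann_whitney(a, b)
        expect_equal(got$p_value, oracle_mw_p(a, b),
                     info = paste("na =", na, "nb =", nb, "rep =", rep))
      }
    }
  }
})

test_that("Mann-Whitney agrees with base R on tie-free data", {
  set.seed(104)
  a <- rnorm(6); b <- rnorm(5, 1)
  got <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(got$p_value, ref$p.value)
  # normal branch close to base R's corrected approximation at larger n
  a <- rnorm(30); b <- rnorm(25, 0.5)
  got <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("Kruskal-Wallis reproduces the hand-computed H and exact p", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(groups)
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2L)
  ref <- kruskal.test(unlist(groups), rep(1:3, each = 3))
  expect_equal(kw$p_value, ref$p.value)

  # only the 3! block-preserving arrangements of 1680 reach H = 7.2
  kw_ex <- kruskal_wallis(groups, exact = TRUE)
  expect_equal(kw_ex$p_value, 6 / 1680)

  # identical groups: H = 0, p = 1
  kw0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  # all values identical: degenerate
  expect_true(kruskal_wallis(list(c(1, 1), c(1, 1)))$degenerate)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
})

test_that("exact Kruskal-Wallis p matches the permutation oracle", {
  set.seed(105)
  for (sizes in list(c(3, 3), c(2, 3, 3), c(2, 2, 2, 2))) {
    for (rep in 1:4) {
      groups <- lapply(sizes, function(n) sample(1:4, n, replace = TRUE))
      if (length(unique(unlist(groups))) == 1L) groups[[1]][1] <- 5
      got <- kruskal_wallis(groups, exact = TRUE)
      expect_equal(got$statistic, oracle_kw_h(groups))
      expect_equal(got$p_value, oracle_kw_p(groups),
                   info = paste(sizes, collapse = "/"))
    }
  }
})

test_that("Dunn z-values match the direct formula and are label-symmetric", {
  groups <- list(g1 = c(1, 2), g2 = c(3, 4), g3 = c(5, 6))
  d <- dunns_test(groups)
  # mean ranks 1.5 / 3.5 / 5.5, N = 6, no ties
  expect_equal(d$z[d$group_i == "g1" & d$group_j == "g2"],
               -2 / sqrt(3.5 * (1 / 2 + 1 / 2)))
  for (m in seq_len(nrow(d))) {
    i <- match(d$group_i[m], names(groups))
    j <- match(d$group_j[m], names(groups))
    expect_equal(d$z[m], oracle_dunn_z(groups, i, j))
  }
  expect_true(all(d$p_adj >= d$p_raw))

  # relabeling groups leaves |z| invariant
  d_rev <- dunns_test(rev(groups))
  expect_setequal(round(abs(d$z), 12), round(abs(d_rev$z), 12))

  # identical groups: z = 0, p = 1
  d0 <- dunns_test(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_raw, 1)
})

test_that("Dunn with ties matches the tie-corrected formula oracle", {
  set.seed(106)
  groups <- list(a = sample(1:3, 6, TRUE), b = sample(1:3, 4, TRUE),
                 c = sample(1:3, 5, TRUE))
  d <- dunns_test(groups)
  for (m in seq_len(nrow(d))) {
    i <- match(d$group_i[m], names(groups))
    j <- match(d$group_j[m], names(groups))
    expect_equal(d$z[m], oracle_dunn_z(groups, i, j))
  }
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(107)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman correlation matches hand-derived values", {
  expect_equal(spearman_rank(1:10, 1:10)$rho, 1)
  expect_equal(spearman_rank(1:10, 10:1)$rho, -1)
  sp <- spearman_rank(1:5, c(2, 1, 4, 3, 5))
  expect_equal(sp$rho, 0.8)  # 1 - 6 * 4 / (5 * 24)
  expect_equal(sp$rho_sq, 0.64)
  ref <- cor.test(1:5, c(2, 1, 4, 3, 5), method = "spearman")
  expect_equal(sp$rho, unname(ref$estimate))
  expect_error(spearman_rank(rep(1, 5), 1:5), "degenerate")
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
})

test_that("median CI uses binomial order statistics", {
  ci <- median_ci(1:100)
  expect_equal(ci$median, 50.5)
  expect_equal(ci$ci_low, 40)   # qbinom(0.025, 100, 0.5) = 40
  expect_equal(ci$ci_high, 61)  # 100 + 1 - 40
  expect_false(ci$degenerate)

  const <- median_ci(rep(7, 20))
  expect_equal(c(const$ci_low, const$ci_high), c(7, 7))

  # nested coverage: 99% interval contains the 95% interval
  set.seed(108)
  x <- rnorm(40)
  ci95 <- median_ci(x, 0.95)
  ci99 <- median_ci(x, 0.99)
  expect_lte(ci99$ci_low, ci95$ci_low)
  expect_gte(ci99$ci_high, ci95$ci_high)

  small <- median_ci(1:4)
  expect_true(small$degenerate)
  expect_equal(c(small$ci_low, small$ci_high), c(1, 4))
})

test_that("rank tests are invariant to common positive scaling", {
  set.seed(109)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(3 * x, 3 * y)$p_value)
  a <- rexp(7); b <- rexp(6)
  expect_equal(mann_whitney(a, b)$p_value,
               mann_whitney(10 * a, 10 * b)$p_value)
  g <- list(rnorm(5), rnorm(4), rnorm(6))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, `*`, 5))$statistic)
})

test_that("significance codes follow the study's scheme", {
  expect_equal(significance_code(c(0.2, 0.04, 0.009, 0.0009, NA)),
               c("ns", "*", "**", "***", NA))
})
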