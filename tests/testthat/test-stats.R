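test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(c(5, 5, 5, 5))$p_value, 1)

  r <- fisher_exact(c(10, 0, 0, 10))
  expect_equal(r$p_value, fisher_p_enum(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  r2 <- fisher_exact(c(7, 3, 3, 7))
  expect_equal(r2$p_value, fisher_p_enum(7, 3, 3, 7), tolerance = 1e-12)

  # a modest exhaustive sweep; the full total <= 20 sweep runs in acceptance
  for (total in c(8, 12)) {
    for (a in 0:total) for (b in 0:(total - a)) for (cc in 0:(total - a - b)) {
      d <- total - a - b - cc
      m <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      expect_equal(fisher_exact(m)$p_value, fisher_p_enum(a, b, cc, d),
                   tolerance = 1e-9,
                   info = sprintf("[%d %d; %d %d]", a, b, cc, d))
    }
  }
})

test_that("Fisher's test is symmetric under transpose and row swap", {
  tab <- matrix(c(9, 4, 2, 11), 2, byrow = TRUE)
  p <- fisher_exact(tab)$p_value
  expect_equal(fisher_exact(t(tab))$p_value, p)
  expect_equal(fisher_exact(tab[2:1, ])$p_value, p)
  expect_error(fisher_exact(c(0, 0, 3, 4)), "margin")
})

test_that("Mann-Whitney U handles separation, identity, and exact enumeration", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)

  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.99)

  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(5)
    y <- rnorm(5, 0.5)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_p_enum(x, y),
                 tolerance = 1e-12)
  }
})

test_that("ANOVA with Bonferroni reproduces hand-computed values", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- anova_bonferroni(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # two groups: F is the square of the pooled t statistic
  set.seed(22)
  x <- rnorm(10)
  y <- rnorm(12, 1)
  r2 <- anova_bonferroni(list(x = x, y = y))
  t_stat <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(r2$statistic, unname(t_stat)^2, tolerance = 1e-10)

  # 3x3 toy: SSB = 42 (df 2), SSW = 6 (df 6) -> F = 21
  toy <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  r3 <- anova_bonferroni(toy)
  expect_equal(r3$statistic, 21, tolerance = 1e-10)
  expect_equal(r3$p_value, pf(21, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(nrow(r3$comparisons), 3L)
  expect_true(all(r3$comparisons$p_adj >= 0 & r3$comparisons$p_adj <= 1))
})

test_that("Kruskal-Wallis H and DSCF match manual rank arithmetic", {
  toy <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  r <- kruskal_steel_dwass(toy)
  # rank sums 6/15/24 over N = 9: H = 12/90 * (36+225+576)/3 - 30 = 7.2
  expect_equal(r$statistic, 7.2, tolerance = 1e-10)

  # pairwise DSCF statistic from the direct formula, pair re-ranked alone
  w <- 6                         # rank sum of group a within the (a, b) pair
  e <- 3 * 7 / 2
  v <- 3 * 3 / 12 * 7
  stat_manual <- abs((w - e) / sqrt(v)) * sqrt(2)
  ab <- r$comparisons[r$comparisons$comparison == "a vs b", ]
  expect_equal(ab$statistic, stat_manual, tolerance = 1e-10)
  expect_equal(ab$p_adj,
               ptukey(stat_manual, 3, Inf, lower.tail = FALSE),
               tolerance = 1e-10)

  flat <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r0 <- kruskal_steel_dwass(flat)
  expect_lt(r0$statistic, 1e-9)
  expect_true(all(r0$comparisons$stars == "NS"))
})

test_that("DSCF adjusted p-values are permutation-invariant in group order", {
  set.seed(23)
  groups <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  p1 <- sort(kruskal_steel_dwass(groups)$comparisons$p_adj)
  p2 <- sort(kruskal_steel_dwass(groups[c(3, 1, 2)])$comparisons$p_adj)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("Steel's many-to-one comparisons flag only shifted treatments", {
  ctrl <- c(1.1, 1.3, 0.9, 1.2, 1.0, 1.15, 0.95, 1.25, 1.05, 1.18)
  r_same <- kruskal_steel(list(ctrl = ctrl, t1 = ctrl + 1e-9,
                               t2 = ctrl - 1e-9), 1)
  expect_true(all(r_same$comparisons$stars == "NS"))

  shifted <- list(ctrl = ctrl, t1 = ctrl + 10, t2 = ctrl + 12)
  r_shift <- kruskal_steel(shifted, 1)
  expect_true(all(r_shift$comparisons$p_adj < 0.05))

  mixed <- list(ctrl = ctrl, t1 = ctrl + 10, t2 = ctrl)
  r_mix <- kruskal_steel(mixed, 1)
  cmp <- r_mix$comparisons
  expect_lt(cmp$p_adj[cmp$comparison == "t1 vs ctrl"], 0.05)
  expect_gt(cmp$p_adj[cmp$comparison == "t2 vs ctrl"], 0.05)

  expect_error(kruskal_steel(shifted, 9), "out of range")
  expect_error(kruskal_steel(shifted[1:2], 1), "at least two treatment")
})

test_that("significance stars follow the published thresholds", {
  expect_equal(pulsesong:::significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("NS", "*", "**", "***"))
})
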