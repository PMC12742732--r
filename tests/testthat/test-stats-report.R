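test_that("Shapiro gate is calibrated on normal data and rejects bimodal data", {
  rej <- vapply(1:500, function(seed) {
    set.seed(seed)
    shapiro_gate(list(g = rnorm(30)))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
  set.seed(1)
  bimodal <- c(rnorm(15, -5, 0.1), rnorm(15, 5, 0.1))
  expect_false(shapiro_gate(list(g = bimodal))$normal)
  # degenerate constant sample: flagged non-normal, no crash
  const <- shapiro_gate(list(g = rep(1, 10)))
  expect_false(const$normal)
  expect_error(shapiro_gate(list(g = c(1, 2))), class = "topobind_invalid_config")
})

test_that("Mann-Whitney exact p-values equal full enumeration for small samples", {
  res <- mann_whitney_one_tailed(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(res$p_value, 1 / 20)
  expect_equal(res$statistic, 0)
  set.seed(42)
  for (na in 2:6) {
    for (nb in c(2, 4, 6)) {
      a <- round(rnorm(na), 3); b <- round(rnorm(nb, 0.5), 3)
      for (tail in c("less", "greater", "two.sided")) {
        got <- mann_whitney_one_tailed(a, b, tail)$p_value
        expect_equal(got, oracle_mw_exact(a, b, tail), tolerance = 1e-12,
                     info = paste(na, nb, tail))
      }
    }
  }
  # identical samples: one-sided p is at least 0.5 either way
  x <- c(2, 4, 6, 8)
  expect_gte(mann_whitney_one_tailed(x, x, "less")$p_value, 0.5)
  expect_gte(mann_whitney_one_tailed(x, x, "greater")$p_value, 0.5)
  expect_error(mann_whitney_one_tailed(numeric(0), x),
               class = "topobind_invalid_config")
})

test_that("Mann-Whitney one-tailed power exceeds 0.9 at d = 1.2, n = 30", {
  rej <- vapply(1:1000, function(seed) {
    set.seed(seed)
    mann_whitney_one_tailed(rnorm(30, 1.2), rnorm(30), "greater")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("Kruskal-Wallis H and epsilon-squared match direct rank arithmetic", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  res <- kruskal_wallis_epsilon2(g)
  H <- oracle_kruskal_H(g)
  expect_equal(res$statistic, H, tolerance = 1e-12)
  expect_equal(res$effect_size, H * 7 / 35, tolerance = 1e-12)
  expect_equal(res$magnitude, "large")
  # identically distributed groups: H = 0 under ties
  same <- list(a = c(1, 2), b = c(1, 2), c = c(1, 2))
  res0 <- kruskal_wallis_epsilon2(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$effect_size, 0)
  expect_error(kruskal_wallis_epsilon2(list(a = 1:3)),
               class = "topobind_invalid_config")
})

test_that("epsilon-squared is bounded and invariant under monotone transforms", {
  set.seed(13)
  for (i in 1:10) {
    g <- list(rnorm(8), rnorm(8, 1), rnorm(8, -0.5))
    e <- kruskal_wallis_epsilon2(g)$effect_size
    expect_gte(e, 0); expect_lte(e, 1)
    g2 <- lapply(g, function(v) exp(v))
    expect_equal(kruskal_wallis_epsilon2(g2)$effect_size, e, tolerance = 1e-12)
  }
})

test_that("Pearson correlation handles exact and degenerate cases", {
  expect_equal(pearson_corr(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_corr(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_true(is.na(pearson_corr(c(1, 1, 1), c(1, 2, 3))$r))
  expect_error(pearson_corr(1:3, 1:4), class = "topobind_invalid_config")
})

test_that("Pearson estimate recovers rho = -0.5 on bivariate normal draws", {
  rs <- vapply(1:1000, function(seed) {
    set.seed(seed)
    x <- rnorm(30)
    y <- -0.5 * x + sqrt(1 - 0.25) * rnorm(30)
    pearson_corr(x, y)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.5)), 0.05)
})

test_that("Wilcoxon power analysis returns n = 33 for the reference design", {
  res <- wilcoxon_power_n(d = 0.6, alpha = 0.05, power = 0.95, tail = "one.sided")
  expect_equal(res$n_are, 33L)
  # monotone in effect size
  expect_lt(wilcoxon_power_n(3.0)$n_are, wilcoxon_power_n(0.6)$n_are)
  expect_lt(wilcoxon_power_n(0.8)$n_are, wilcoxon_power_n(0.6)$n_are)
  expect_error(wilcoxon_power_n(-1), class = "topobind_invalid_config")
  expect_error(wilcoxon_power_n(0.6, alpha = 0.05, power = 1),
               class = "topobind_invalid_config")
})

test_that("simulation and ARE routes agree to within 2 subjects", {
  for (d in c(0.6, 0.8)) {
    res <- wilcoxon_power_n(d, n_sims = 1500, seed = 7)
    expect_lte(abs(res$n_sim - res$n_are), 2)
  }
})
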