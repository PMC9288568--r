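test_that("t tests agree with the reference implementation and carry d", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    ref <- t.test(x, mu = 0.2)
    res <- one_sample_t(x, 0.2)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$df, unname(ref$parameter))
    # d recomputed as t / sqrt(n) equals mean/SD exactly
    expect_equal(res$effect_size, res$statistic / sqrt(length(x)),
                 tolerance = 1e-12)
  }
  y <- rnorm(20); z <- rnorm(20)
  refp <- t.test(y, z, paired = TRUE)
  resp <- paired_t(y, z)
  expect_equal(resp$statistic, unname(refp$statistic), tolerance = 1e-12)
  expect_equal(resp$p_value, refp$p.value, tolerance = 1e-12)
  expect_equal(resp$effect_label, "d_z")

  one_sided <- one_sample_t(y, alternative = "greater")
  expect_equal(one_sided$p_value,
               t.test(y, alternative = "greater")$p.value, tolerance = 1e-12)
  expect_error(one_sample_t(rep(1, 3), 1), "zero variance")
})

test_that("effect sizes recomputed from t and n match reported conventions", {
  expect_equal(round(cohen_d_from_t(10.32, 300), 2), 0.60)
  expect_equal(round(cohen_d_from_t(3.60, 78), 2), 0.41)
  expect_equal(cohen_d_from_t(0, 50), 0)
})

test_that("constant data give all-zero F statistics", {
  d <- make_anova_fixture(6, "mixed")
  d$y <- 1
  tab <- anova_2x2(d, "y", "subject", "A", "B", design = "mixed")
  expect_equal(tab$F, c(0, 0, 0))
  expect_equal(tab$pes, c(0, 0, 0))
})

test_that("mixed and within 2x2 tables match the aov oracle and t-square identities", {
  set.seed(15)
  for (i in 1:10) {
    for (design in c("mixed", "within")) {
      d <- make_anova_fixture(sample(6:15, 1), design,
                              effects = c(a = runif(1, -1, 1),
                                          b = runif(1, -1, 1),
                                          ab = runif(1, -1, 1)))
      tab <- anova_2x2(d, "y", "subject", "A", "B", design = design)
      oracle <- aov_2x2_oracle(d, design)
      expect_equal(tab$F, oracle$F, tolerance = 1e-10)
      expect_equal(tab$p, oracle$p, tolerance = 1e-10)
      # partial eta squared matches its defining identity
      expect_equal(tab$pes, tab$ss / (tab$ss + tab$ss_error),
                   tolerance = 1e-12)

      if (design == "mixed") {
        subj_means <- aggregate(y ~ subject + A, d, mean)
        tt <- t.test(y ~ A, subj_means, var.equal = TRUE)
        expect_equal(tab$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
        diffs <- aggregate(y ~ subject + A, d,
                           function(v) v[2] - v[1])
        td <- t.test(y ~ A, diffs, var.equal = TRUE)
        expect_equal(tab$F[3], unname(td$statistic)^2, tolerance = 1e-10)
      }
    }
  }
  d <- make_anova_fixture(6, "mixed")
  expect_error(anova_2x2(d[-1, ], "y", "subject", "A", "B", "mixed"),
               "unbalanced")
})

test_that("pearson_r matches cor.test and recovers a known correlation", {
  x <- c(1, 3, 2, 5, 4, 7, 6)
  expect_equal(pearson_r(x, x)$statistic, 1)
  expect_equal(pearson_r(x, -x)$statistic, -1)
  set.seed(16)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  ref <- cor.test(a, b)
  res <- pearson_r(a, b)
  expect_equal(res$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  z <- rmvnorm_chol(10000, matrix(c(1, 0.4, 0.4, 1), 2))
  expect_lt(abs(pearson_r(z[, 1], z[, 2])$statistic - 0.4), 0.02)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("the independent-correlations z test is antisymmetric and matches its closed form", {
  expect_equal(fisher_z_independent(0.4, 30, 0.4, 50)$statistic, 0)
  a <- fisher_z_independent(0.2, 40, 0.5, 60)
  b <- fisher_z_independent(0.5, 60, 0.2, 40)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # frozen closed-form value for the r = .29 (n 63) vs .63 (n 78) contrast
  expect_equal(fisher_z_independent(0.29, 63, 0.63, 78)$statistic,
               -2.556795, tolerance = 1e-5)
  expect_error(fisher_z_independent(1, 30, 0.5, 30))
})

test_that("dependent non-overlapping tests are zero under symmetric equality", {
  for (method in c("pearson_filon_1898", "fisher_1925")) {
    res <- dependent_nonoverlapping_z(0.4, 0.4, 0.3, 0.2, 0.2, 0.3, 100,
                                      method = method)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1)
  }
  expect_error(
    dependent_nonoverlapping_z(0.9, -0.9, 0.9, 0.9, 0.9, 0.9, 100),
    "positive semi-definite")
})

test_that("dependent tests hold their size under the null", {
  set.seed(17)
  R <- matrix(c(1, 0.4, 0.3, 0.2,
                0.4, 1, 0.2, 0.3,
                0.3, 0.2, 1, 0.4,
                0.2, 0.3, 0.4, 1), 4)
  n <- 200
  rejections <- replicate(2000, {
    x <- rmvnorm_chol(n, R)
    r <- cor(x)
    z <- dependent_nonoverlapping_z(r[1, 2], r[3, 4], r[1, 3], r[1, 4],
                                    r[2, 3], r[2, 4], n,
                                    method = "fisher_1925")
    z$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("with zero cross-correlations the dependent test approaches the independent one", {
  z_dep <- dependent_nonoverlapping_z(0.3, 0.5, 0, 0, 0, 0, 5000,
                                      method = "fisher_1925")
  z_ind <- fisher_z_independent(0.3, 5000, 0.5, 5000)
  expect_equal(z_dep$statistic, z_ind$statistic, tolerance = 0.01)
})

test_that("model comparisons satisfy the AIC identity and detect a framing effect", {
  set.seed(18)
  n <- 80
  d <- data.frame(
    participant_id = rep(1:n, each = 2),
    framing = rep(c("gain", "loss"), n),
    metacog_internal_bias = rep(rnorm(n, -6, 10), each = 2)
  )
  u <- rep(rnorm(n, 0, 1), each = 2)
  d$reminder_bias <- 1 + u - 0.02 * d$metacog_internal_bias +
    0.7 * (d$framing == "gain") + rnorm(2 * n, 0, 1.5)

  m0 <- fit_bias_lmm(reminder_bias ~ 1, d)
  m1 <- fit_bias_lmm(reminder_bias ~ framing, d)
  cmp <- compare_models(m0, m1)
  expect_equal(cmp$chisq,
               diff(-cmp$models$AIC) + 2 * cmp$df, tolerance = 1e-10)
  self <- compare_models(m0, m0)
  expect_equal(self$chisq, 0)
  expect_error(compare_models(m1, m0), "nested")

  # power by simulation for a true additive framing effect of 0.7 points
  hits <- replicate(100, {
    dd <- d
    uu <- rep(rnorm(n, 0, 1), each = 2)
    dd$reminder_bias <- 1 + uu + 0.7 * (dd$framing == "gain") +
      rnorm(2 * n, 0, 1.2)
    a <- fit_bias_lmm(reminder_bias ~ 1, dd)
    b <- fit_bias_lmm(reminder_bias ~ framing, dd)
    compare_models(a, b)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.90)
})

test_that("paired-t sample sizes come from the noncentral t and are minimal", {
  expect_equal(required_n_paired_t(0.41, 0.05, 0.80), 49)
  pw <- function(n, d) {
    tc <- qt(0.975, n - 1)
    pt(tc, n - 1, d * sqrt(n), lower.tail = FALSE) +
      pt(-tc, n - 1, d * sqrt(n))
  }
  for (d in c(0.2, 0.3, 0.41, 0.5)) {
    n <- required_n_paired_t(d, 0.05, 0.80)
    expect_gte(pw(n, d), 0.80)
    expect_lt(pw(n - 1, d), 0.80)
    approx_n <- ((qnorm(0.975) + qnorm(0.80)) / d)^2
    expect_lte(abs(n - approx_n), 3)
  }
  expect_error(required_n_paired_t(-0.2))
})
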