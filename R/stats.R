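new_stat_result <- function(test_name, statistic, df, p_value,
                            effect_size = NULL, effect_label = NULL, n = NULL) {
  out <- list(test_name = test_name, statistic = statistic, df = df,
              p_value = p_value, effect_size = effect_size,
              effect_label = effect_label, n = n)
  class(out) <- "stat_result"
  out
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(round(x$df, 2), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g", x$test_name,
              x$statistic, dfs, x$p_value))
  if (!is.null(x$effect_size)) {
    cat(sprintf(", %s = %.4f", x$effect_label, x$effect_size))
  }
  cat("\n")
  invisible(x)
}

p_from_t <- function(t, df, alternative) {
  switch(alternative,
         two.sided = 2 * stats::pt(-abs(t), df),
         greater = stats::pt(t, df, lower.tail = FALSE),
         less = stats::pt(t, df))
}

#' One-sample and paired t tests with standardized effect sizes
#'
#' `one_sample_t()` tests the mean of `x` against `mu0` and reports
#' Cohen's d = mean / SD (equivalently t / sqrt(n)). `paired_t()` is the
#' one-sample test on the pairwise differences, reporting d_z, the
#' conventional effect size for paired designs.
#'
#' @param x,y Numeric vectors (`y` paired with `x`).
#' @param mu0 Null value for the mean (default 0).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `stat_result` with statistic, df = n - 1, p, and effect size.
#' @export
#' @examples
#' set.seed(1); one_sample_t(rnorm(30, 0.5))
one_sample_t <- function(x, mu0 = 0, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  n <- length(x)
  stopifnot(n >= 2)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: t statistic undefined", call. = FALSE)
  t <- (mean(x) - mu0) / (s / sqrt(n))
  new_stat_result("one-sample t", t, n - 1,
                  p_from_t(t, n - 1, alternative),
                  effect_size = (mean(x) - mu0) / s, effect_label = "d", n = n)
}

#' @rdname one_sample_t
#' @export
paired_t <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y))
  res <- one_sample_t(x - y, 0, alternative)
  res$test_name <- "paired t"
  res$effect_label <- "d_z"
  res
}

#' Standardized effect size from a t statistic
#'
#' For one-sample and paired designs, Cohen's d (or d_z) equals
#' t / sqrt(n). Useful for recomputing effect sizes from reported summary
#' statistics.
#'
#' @param t t statistic.
#' @param n Sample size (pairs, for a paired design).
#' @return Effect size d = t / sqrt(n).
#' @export
#' @examples
#' cohen_d_from_t(6.49, 63)  # 0.82
cohen_d_from_t <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

#' Balanced 2 x 2 ANOVA (mixed or fully within-participants)
#'
#' Sums-of-squares decomposition for a balanced two-by-two design with one
#' observation per cell per subject, computed from its closed forms. In
#' the `"mixed"` design factor A is between-participants and factor B
#' within; in `"within"` both factors are within-participants (each
#' effect tested against its own subject-interaction error term). Partial
#' eta squared is SS_effect / (SS_effect + SS_error) per row.
#'
#' @param data Long data frame.
#' @param dv,subject,between,within Column names. For `design = "within"`,
#'   `between` names the second within factor.
#' @param design `"mixed"` or `"within"`.
#' @return An `anova_table` data frame: one row per effect (A, B, A:B)
#'   with `ss`, `df`, `ss_error`, `df_error`, `F`, `p`, `pes`.
#' @export
anova_2x2 <- function(data, dv, subject, between, within,
                      design = c("mixed", "within")) {
  design <- match.arg(design)
  y <- data[[dv]]
  s <- factor(data[[subject]])
  A <- factor(data[[between]])
  B <- factor(data[[within]])
  if (nlevels(A) != 2 || nlevels(B) != 2) {
    stop("both factors must have exactly two levels", call. = FALSE)
  }
  complete <- if (design == "within") {
    all(table(s, A, B) == 1)
  } else {
    # subjects nested in A: one observation per subject per within level
    all(table(s, B) == 1) && all(rowSums(table(s, A) > 0) == 1)
  }
  if (!complete) {
    stop("unbalanced data: expected one observation per subject per cell",
         call. = FALSE)
  }

  gm <- mean(y)
  ss <- function(means, n_per) sum(n_per * (means - gm)^2)
  mA <- tapply(y, A, mean); nA <- table(A)
  mB <- tapply(y, B, mean); nB <- table(B)
  mAB <- tapply(y, list(A, B), mean); nAB <- table(A, B)
  mS <- tapply(y, s, mean); nS <- table(s)

  ss_A <- ss(mA, nA)
  ss_B <- ss(mB, nB)
  ss_AB <- sum(nAB * (mAB - outer(mA - gm, mB - gm, "+") - gm)^2)
  ss_S <- ss(mS, nS)

  if (design == "mixed") {
    # subjects nested in A: between error = subjects-within-A
    ss_err_between <- ss_S - ss_A
    df_err_between <- nlevels(s) - 2
    ss_tot <- sum((y - gm)^2)
    ss_err_within <- ss_tot - ss_S - ss_B - ss_AB
    df_err_within <- nlevels(s) - 2
    tab <- data.frame(
      effect = c(between, within, paste0(between, ":", within)),
      ss = c(ss_A, ss_B, ss_AB),
      df = c(1, 1, 1),
      ss_error = c(ss_err_between, ss_err_within, ss_err_within),
      df_error = c(df_err_between, df_err_within, df_err_within)
    )
  } else {
    # subject-by-factor interaction error terms; each subject x level cell
    # holds two observations (the two levels of the other factor)
    mSA <- tapply(y, list(s, A), mean)
    mSB <- tapply(y, list(s, B), mean)
    ss_SA <- 2 * sum((mSA - outer(mS - gm, mA - gm, "+") - gm)^2)
    ss_SB <- 2 * sum((mSB - outer(mS - gm, mB - gm, "+") - gm)^2)
    ss_tot <- sum((y - gm)^2)
    ss_SAB <- ss_tot - ss_S - ss_A - ss_B - ss_AB - ss_SA - ss_SB
    ns <- nlevels(s)
    tab <- data.frame(
      effect = c(between, within, paste0(between, ":", within)),
      ss = c(ss_A, ss_B, ss_AB),
      df = c(1, 1, 1),
      ss_error = c(ss_SA, ss_SB, ss_SAB),
      df_error = c(ns - 1, ns - 1, ns - 1)
    )
  }
  # a zero effect sum of squares gives F = 0 even if the error SS is also
  # zero (degenerate constant data)
  tab$F <- ifelse(tab$ss <= 1e-12, 0,
                  (tab$ss / tab$df) / (tab$ss_error / tab$df_error))
  tab$p <- stats::pf(tab$F, tab$df, tab$df_error, lower.tail = FALSE)
  tab$pes <- ifelse(tab$ss <= 1e-12, 0, tab$ss / (tab$ss + tab$ss_error))
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors, n >= 3.
#' @param alternative Sidedness of the test.
#' @return A `stat_result` with the correlation as both statistic and
#'   effect size (`r`), df = n - 2.
#' @export
pearson_r <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  res <- new_stat_result("Pearson correlation", r, n - 2,
                         p_from_t(t, n - 2, alternative),
                         effect_size = r, effect_label = "r", n = n)
  res
}

#' Compare two correlations from independent samples (Fisher z)
#'
#' Fisher's z test for correlations measured on two independent groups:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to
#' the standard normal.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Group sizes, each > 3.
#' @param alternative Sidedness (default two-sided).
#' @return A `stat_result` with the z statistic.
#' @export
#' @examples
#' fisher_z_independent(0.29, 63, 0.63, 78)  # z about -2.56
fisher_z_independent <- function(r1, n1, r2, n2,
                                 alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  stopifnot(n1 > 3, n2 > 3, abs(r1) < 1, abs(r2) < 1)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  new_stat_result("Fisher z (independent correlations)", z, NA_real_, p,
                  n = n1 + n2)
}

#' Compare two dependent, non-overlapping correlations
#'
#' Tests `r12 = r34` when all four variables are measured on the same
#' sample and the two correlations share no variable. Two classical
#' statistics are available. `"pearson_filon_1898"` works on the raw
#' correlation scale:
#' `z = sqrt(n) (r12 - r34) / sqrt((1-r12^2)^2 + (1-r34^2)^2 - k)`,
#' where `k` collects the covariance contribution of the four
#' cross-correlations. `"fisher_1925"` applies the same covariance
#' structure on the Fisher-z scale:
#' `z = (atanh(r12) - atanh(r34)) sqrt((n-3) / (2 - 2c))` with
#' `c = k / (2 (1-r12^2)(1-r34^2))`. With all cross-correlations zero both
#' reduce to the independent-samples comparison at equal n.
#'
#' @param r12,r34 The correlations being compared.
#' @param r13,r14,r23,r24 Cross-correlations among the four variables.
#' @param n Sample size (> 4).
#' @param method `"pearson_filon_1898"` or `"fisher_1925"`.
#' @param alternative Sidedness (default two-sided).
#' @return A `stat_result` with the z statistic.
#' @export
dependent_nonoverlapping_z <- function(r12, r34, r13, r14, r23, r24, n,
                                       method = c("pearson_filon_1898",
                                                  "fisher_1925"),
                                       alternative = "two.sided") {
  method <- match.arg(method)
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  stopifnot(n > 4)
  R <- matrix(c(1, r12, r13, r14,
                r12, 1, r23, r24,
                r13, r23, 1, r34,
                r14, r24, r34, 1), 4, 4)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("inconsistent correlation matrix (not positive semi-definite)",
         call. = FALSE)
  }
  k <- (r13 - r23 * r12) * (r24 - r23 * r34) +
       (r14 - r13 * r34) * (r23 - r13 * r12) +
       (r13 - r14 * r34) * (r24 - r14 * r12) +
       (r14 - r12 * r24) * (r23 - r24 * r34)
  if (method == "pearson_filon_1898") {
    z <- sqrt(n) * (r12 - r34) /
      sqrt((1 - r12^2)^2 + (1 - r34^2)^2 - k)
    name <- "Pearson-Filon z (dependent non-overlapping correlations)"
  } else {
    c_z <- k / (2 * (1 - r12^2) * (1 - r34^2))
    z <- (atanh(r12) - atanh(r34)) * sqrt((n - 3) / (2 - 2 * c_z))
    name <- "Fisher z (dependent non-overlapping correlations)"
  }
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  new_stat_result(name, z, NA_real_, p, n = n)
}

#' Random-intercept mixed models on reminder bias and their comparison
#'
#' `fit_bias_lmm()` fits a linear mixed model with a participant random
#' intercept by maximum likelihood (not REML, so that models differing in
#' fixed effects are comparable by AIC and likelihood-ratio test).
#' `compare_models()` compares two nested ML fits: the chi-square is twice
#' the log-likelihood difference with df equal to the difference in number
#' of parameters, and by construction chi-square = delta-AIC + 2 df.
#'
#' @param formula Model formula for the fixed effects; the participant
#'   random intercept `(1 | participant_id)` is appended automatically if
#'   absent.
#' @param data Long data frame (one row per participant x framing).
#' @param m0,m1 Two fits from `fit_bias_lmm()`, `m0` nested in `m1`.
#' @return `fit_bias_lmm()`: an `lme4` fit. `compare_models()`: a
#'   `model_comparison` list with per-model parameters, log-likelihood and
#'   AIC, plus the LRT chi-square, df and p.
#' @export
#' @examples
#' \dontrun{
#' m0 <- fit_bias_lmm(reminder_bias ~ 1, measures)
#' m1 <- fit_bias_lmm(reminder_bias ~ framing, measures)
#' compare_models(m0, m1)
#' }
fit_bias_lmm <- function(formula, data) {
  f <- stats::as.formula(formula)
  if (!grepl("participant_id", paste(deparse(f), collapse = " "))) {
    f <- stats::update(f, . ~ . + (1 | participant_id))
  }
  lme4::lmer(f, data = data, REML = FALSE)
}

#' @rdname fit_bias_lmm
#' @export
compare_models <- function(m0, m1) {
  ll0 <- as.numeric(stats::logLik(m0)); k0 <- attr(stats::logLik(m0), "df")
  ll1 <- as.numeric(stats::logLik(m1)); k1 <- attr(stats::logLik(m1), "df")
  if (k1 < k0) stop("m0 must be nested in (no larger than) m1", call. = FALSE)
  chisq <- max(0, 2 * (ll1 - ll0))
  df <- k1 - k0
  out <- list(
    models = data.frame(model = c("m0", "m1"), k = c(k0, k1),
                        logLik = c(ll0, ll1),
                        AIC = c(2 * k0 - 2 * ll0, 2 * k1 - 2 * ll1)),
    chisq = chisq, df = df,
    p_value = if (df == 0) NA_real_ else
      stats::pchisq(chisq, df, lower.tail = FALSE)
  )
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$models, row.names = FALSE)
  cat(sprintf("LRT: chi-square(%d) = %.3f, p = %.4g\n",
              x$df, x$chisq, x$p_value))
  invisible(x)
}

#' Sample size for a paired t test via the noncentral t distribution
#'
#' Smallest number of pairs n such that a paired t test with df = n - 1,
#' noncentrality `d_z * sqrt(n)` and level `alpha` reaches the target
#' power, computed exactly from the noncentral t distribution.
#'
#' @param d_z Standardized effect size of the pairwise differences (> 0).
#' @param alpha Significance level.
#' @param power Target power (alpha < power < 1).
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @return Smallest integer n meeting the target.
#' @export
#' @examples
#' required_n_paired_t(0.41, 0.05, 0.80)  # 49
required_n_paired_t <- function(d_z, alpha = 0.05, power = 0.80,
                                alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(d_z > 0, alpha > 0, alpha < 1, power > alpha, power < 1)
  pw <- function(n) {
    df <- n - 1
    ncp <- d_z * sqrt(n)
    if (alternative == "two.sided") {
      tc <- stats::qt(1 - alpha / 2, df)
      stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
    } else {
      tc <- stats::qt(1 - alpha, df)
      stats::pt(tc, df, ncp, lower.tail = FALSE)
    }
  }
  n <- 2
  while (pw(n) < power) n <- n + 1
  n
}
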