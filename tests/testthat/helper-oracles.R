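# Independent oracles used across the suite.

# All bin partitions (nine length-2 bins, one length-1, over positions
# lo..hi) consistent with a target set: returns the short-bin slots for
# which every bin contains exactly one target.
consistent_partitions <- function(positions, lo = 7L, hi = 25L,
                                  n_bins = 10L) {
  ok <- integer(0)
  for (short in seq_len(n_bins)) {
    lengths <- rep(2L, n_bins)
    lengths[short] <- 1L
    ends <- lo - 1L + cumsum(lengths)
    starts <- ends - lengths + 1L
    counts <- vapply(seq_len(n_bins), function(b) {
      sum(positions >= starts[b] & positions <= ends[b])
    }, integer(1))
    if (all(counts == 1L)) ok <- c(ok, short)
  }
  ok
}

# Brute-force psychometric oracle: profile grid search of the logistic
# log-likelihood over location (step `loc_step`) and a dense slope grid,
# returning the clamped location at the grid maximum and the maximum
# log-likelihood.
grid_aip_oracle <- function(offers, choices, bounds = c(1, 9),
                            loc_step = 0.005) {
  locs <- seq(bounds[1], bounds[2], by = loc_step)
  slopes <- exp(seq(log(0.01), log(50), length.out = 120))
  y1 <- as.numeric(choices)
  y0 <- 1 - y1
  best_ll <- -Inf
  best_loc <- NA_real_
  for (s in slopes) {
    eta <- s * outer(locs, offers, function(l, o) o - l)
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- as.vector(log(p) %*% y1 + log1p(-p) %*% y0)
    i <- which.max(ll)
    if (ll[i] > best_ll) {
      best_ll <- ll[i]
      best_loc <- locs[i]
    }
  }
  list(aip = best_loc, log_likelihood = best_ll)
}

# Balanced 2x2 fixture: one value per subject per within level
make_anova_fixture <- function(n_per_group = 8, design = "mixed",
                               effects = c(a = 0, b = 0, ab = 0),
                               subj_sd = 1, noise_sd = 1) {
  if (design == "mixed") {
    n <- 2 * n_per_group
    subj <- rep(seq_len(n), each = 2)
    A <- rep(rep(c("a1", "a2"), each = n_per_group), each = 2)
    B <- rep(c("b1", "b2"), times = n)
    u <- rep(stats::rnorm(n, 0, subj_sd), each = 2)
  } else {
    n <- n_per_group
    subj <- rep(seq_len(n), each = 4)
    A <- rep(rep(c("a1", "a2"), each = 2), times = n)
    B <- rep(c("b1", "b2"), times = 2 * n)
    u <- rep(stats::rnorm(n, 0, subj_sd), each = 4)
  }
  y <- u + effects["a"] * (A == "a2") + effects["b"] * (B == "b2") +
    effects["ab"] * (A == "a2") * (B == "b2") +
    stats::rnorm(length(A), 0, noise_sd)
  data.frame(subject = subj, A = A, B = B, y = as.numeric(y))
}

# aov-based oracle for the balanced 2x2 (mixed or within) design
aov_2x2_oracle <- function(data, design = "mixed") {
  data$subject <- factor(data$subject)
  if (design == "mixed") {
    fit <- stats::aov(y ~ A * B + Error(subject), data = data)
    s <- summary(fit)
    between <- s[["Error: subject"]][[1]]
    within <- s[["Error: Within"]][[1]]
    data.frame(
      effect = c("A", "B", "A:B"),
      F = c(between["A", "F value"], within["B", "F value"],
            within["A:B", "F value"]),
      p = c(between["A", "Pr(>F)"], within["B", "Pr(>F)"],
            within["A:B", "Pr(>F)"])
    )
  } else {
    fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = data)
    s <- summary(fit)
    data.frame(
      effect = c("A", "B", "A:B"),
      F = c(s[["Error: subject:A"]][[1]]["A", "F value"],
            s[["Error: subject:B"]][[1]]["B", "F value"],
            s[["Error: subject:A:B"]][[1]]["A:B", "F value"]),
      p = c(s[["Error: subject:A"]][[1]]["A", "Pr(>F)"],
            s[["Error: subject:B"]][[1]]["B", "Pr(>F)"],
            s[["Error: subject:A:B"]][[1]]["A:B", "Pr(>F)"])
    )
  }
}

# Correlated 4-variate normal sample with a given correlation matrix
rmvnorm_chol <- function(n, R) {
  L <- chol(R)
  matrix(stats::rnorm(n * nrow(R)), n) %*% L
}

# Tiny hand-built cohort for screening tests: per-participant accuracy,
# choice pattern and bias are set directly, then expanded into the
# measures/trials tables the screening functions expect.
make_screening_cohort <- function(df, experiment = 1) {
  offers <- if (experiment == 1) 1:9 else 2:8
  measures <- list()
  trials <- list()
  framings <- if (experiment == 1) "gain" else c("gain", "loss")
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    for (fr in framings) {
      measures[[length(measures) + 1L]] <- data.frame(
        participant_id = row$participant_id, framing = fr,
        acc_fi = row$acc_fi, acc_fe = row$acc_fe,
        oip = 5, aip = 5 - row$bias, reminder_bias = row$bias,
        fit_converged = TRUE,
        metacog_internal_bias = if ("metacog" %in% names(df)) row$metacog else 0,
        metacog_external_bias = 0
      )
      choices <- switch(row$pattern,
        increasing = as.integer(offers >= stats::median(offers)),
        decreasing = as.integer(offers <= 4),
        constant = rep(1L, length(offers)))
      trials[[length(trials) + 1L]] <- data.frame(
        participant_id = row$participant_id, experiment = experiment,
        framing = fr, trial_type = "choice", offer_equiv = offers,
        strategy_used = ifelse(choices == 1, "external", "internal"),
        n_hits = 5
      )
    }
  }
  list(measures = do.call(rbind, measures), trials = do.call(rbind, trials))
}
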