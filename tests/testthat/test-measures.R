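test_that("forced-trial accuracy is total hits over total targets", {
  sess <- data.frame(trial_type = rep("forced_internal", 4),
                     n_hits = c(6, 7, 6, 7))
  expect_equal(accuracy(sess, "forced_internal"), 0.65)
  sess$n_hits <- 10
  expect_equal(accuracy(sess, "forced_internal"), 1.0)
  expect_error(accuracy(sess, "forced_external"), "no trials")

  set.seed(8)
  big <- data.frame(trial_type = rep("forced_internal", 1000),
                    n_hits = rbinom(1000, 10, 0.65))
  expect_equal(accuracy(big, "forced_internal"), 0.65, tolerance = 0.01)
})

test_that("loss offers convert to their gain-equivalent values", {
  expect_equal(equivalent_gain_value(-9, "loss", 1), 1)
  expect_equal(equivalent_gain_value(-1, "loss", 1), 9)
  expect_equal(equivalent_gain_value(3, "loss", 2), 7)
  expect_equal(equivalent_gain_value(7, "loss", 2), 3)
  expect_equal(equivalent_gain_value(5, "gain", 1), 5)
  expect_equal(equivalent_gain_value(5, "gain", 2), 5)
  expect_error(equivalent_gain_value(3, "loss", 1), "out of range")
  expect_error(equivalent_gain_value(-3, "loss", 2), "out of range")
  expect_error(equivalent_gain_value(10, "gain", 1), "out of range")
})

test_that("the optimal indifference point balances the two payoffs", {
  expect_equal(compute_oip(0.55, 1.00), 5.5)
  expect_equal(compute_oip(0.90, 0.90), 9)        # ratio 1, clamped high
  expect_equal(compute_oip(0.10, 0.95, bounds = c(2, 8)), 2)  # clamped low
  expect_equal(compute_oip(0.65, 0.95), 10 * 0.65 / 0.95)
  expect_error(compute_oip(0.5, 0), "undefined")
})

test_that("degenerate choice patterns resolve to the offer bounds", {
  expect_equal(fit_aip(1:9, rep(1L, 9))$aip, 1)
  expect_equal(fit_aip(1:9, rep(0L, 9))$aip, 9)
  expect_equal(fit_aip(2:8, rep(1L, 7), bounds = c(2, 8))$aip, 2)
  expect_equal(fit_aip(2:8, rep(0L, 7), bounds = c(2, 8))$aip, 8)
})

test_that("step data put the indifference point inside the step, at the grid optimum", {
  offers <- 2:8
  choices <- as.integer(offers >= 6)
  fit <- fit_aip(offers, choices, bounds = c(2, 8))
  expect_gte(fit$aip, 5)
  expect_lte(fit$aip, 6)
  oracle <- grid_aip_oracle(offers, choices, bounds = c(2, 8))
  expect_equal(fit$aip, oracle$aip, tolerance = 0.01)
  expect_gte(fit$log_likelihood, oracle$log_likelihood - 1e-6)
})

test_that("the psychometric fit matches the brute-force grid oracle", {
  set.seed(9)
  for (i in 1:12) {
    offers <- rep(1:9, each = 3)
    sip <- runif(1, 2.5, 7.5)
    slope <- runif(1, 0.5, 2)
    choices <- rbinom(length(offers), 1, plogis(slope * (offers - sip)))
    if (all(choices == choices[1])) next
    fit <- fit_aip(offers, choices)
    oracle <- grid_aip_oracle(offers, choices)
    expect_gte(fit$log_likelihood, oracle$log_likelihood - 1e-6)
    expect_equal(fit$aip, oracle$aip, tolerance = 0.05)
  }
})

test_that("a reminder choice at the lowest offer pulls interior indifference points down", {
  # holds for interior steps; with a high step the two-parameter MLE can
  # instead flatten the slope and move the location up (see below)
  for (k in 2:7) {
    choices <- as.integer(1:9 >= k)
    before <- fit_aip(1:9, choices)$aip
    choices[1] <- 1L
    after <- fit_aip(1:9, choices)$aip
    expect_lte(after, before + 1e-6)
  }
  # pathological case: the isolated low choice trades slope for location;
  # the fit still agrees with the brute-force likelihood maximizer
  choices <- c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L)
  fit <- fit_aip(1:9, choices)
  oracle <- grid_aip_oracle(1:9, choices)
  expect_equal(fit$aip, oracle$aip, tolerance = 0.06)
  expect_gte(fit$log_likelihood, oracle$log_likelihood - 1e-6)
})

test_that("bias measures follow their sign conventions", {
  expect_equal(reminder_bias(6.2, 4.2), 2.0)
  expect_equal(reminder_bias(5, 5), 0)
  expect_equal(reminder_bias(3, 5), -2)
  expect_equal(metacognitive_bias(60, 0.65), -5)
  expect_equal(metacognitive_bias(80, 0.80), 0)
  expect_equal(metacognitive_bias(95, 0.90), 5)
})

test_that("cohort measures reproduce hand-computed values", {
  # one participant, one framing: 2 forced trials per type, 9 choices
  trials <- rbind(
    data.frame(participant_id = 1, experiment = 1, framing = "gain",
               trial_type = "forced_internal", offer_equiv = NA,
               strategy_used = "internal", n_hits = c(6, 7)),
    data.frame(participant_id = 1, experiment = 1, framing = "gain",
               trial_type = "forced_external", offer_equiv = NA,
               strategy_used = "external", n_hits = c(10, 9)),
    data.frame(participant_id = 1, experiment = 1, framing = "gain",
               trial_type = "choice", offer_equiv = 1:9,
               strategy_used = ifelse(1:9 >= 6, "external", "internal"),
               n_hits = 8)
  )
  trials$conf_internal <- 60
  trials$conf_external <- 90
  m <- compute_measures(trials)
  expect_equal(nrow(m), 1)
  expect_equal(m$acc_fi, 0.65)
  expect_equal(m$acc_fe, 0.95)
  expect_equal(m$oip, 10 * 0.65 / 0.95)
  expect_gte(m$aip, 5); expect_lte(m$aip, 6)
  expect_equal(m$reminder_bias, m$oip - m$aip)
  expect_equal(m$metacog_internal_bias, 60 - 65)
  expect_equal(m$metacog_external_bias, 90 - 95)
})
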