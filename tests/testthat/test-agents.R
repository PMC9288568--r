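test_that("agent parameter invariants are enforced", {
  expect_error(agent_params(1.2, 0.95, subjective_ip = 5))
  expect_error(agent_params(0.6, 0.75, subjective_ip = 5))  # below practice gate
  expect_error(agent_params(0.6, 0.95, subjective_ip = 12))
  expect_error(agent_params(0.6, 0.95, subjective_ip = 5, lapse = 0.6))
  a <- agent_params(0.6, 0.95, subjective_ip = 5)
  expect_s3_class(a, "agent_params")
})

test_that("a zero-variance spec collapses to the location parameters", {
  spec <- population_spec(20, p_internal_sd = 0, p_external_sd = 0,
                          conf_noise_sd = 0, ip_noise_sd = 0,
                          framing_shift_sd = 0, slope_sdlog = 0)
  set.seed(3)
  pop <- sample_population(spec)
  expect_true(all(pop$p_internal == 0.65))
  expect_true(all(pop$p_external == 0.95))
  expect_true(all(pop$conf_internal == 65 - 7))
  expect_true(all(pop$framing_shift == 1.0))
  expect_true(all(pop$choice_slope == 1.5))
  # subjective ip sits a fixed offset below the common optimal point
  expect_true(all(abs(pop$subjective_ip - (10 * 0.65 / 0.95 - 1.5)) < 1e-12))
})

test_that("the default truncated sampler is centred where specified", {
  set.seed(4)
  pop <- sample_population(population_spec(500))
  expect_equal(mean(pop$p_internal), 0.65, tolerance = 0.03)
  expect_true(all(pop$p_external >= 0.8 & pop$p_external <= 1))
  expect_true(all(pop$lapse >= 0 & pop$lapse <= 0.5))
  # confidence offset below true accuracy forces mean underconfidence
  expect_lt(mean(pop$conf_internal - 100 * pop$p_internal), 0)
})

test_that("choice probability is a shifted logistic with lapse floor", {
  a <- agent_params(0.65, 0.95, subjective_ip = 5, framing_shift = 1,
                    choice_slope = 2)
  expect_equal(choice_probability(a, 5, "gain"), 0.5)
  expect_equal(choice_probability(a, 6, "loss"), 0.5)

  no_shift <- agent_params(0.65, 0.95, subjective_ip = 5, framing_shift = 0)
  for (offer in 1:9) {
    expect_equal(choice_probability(no_shift, offer, "gain"),
                 choice_probability(no_shift, offer, "loss"))
  }

  steep <- agent_params(0.65, 0.95, subjective_ip = 5, choice_slope = 50)
  expect_gt(choice_probability(steep, 6, "gain"), 1 - 1e-10)
  expect_lt(choice_probability(steep, 4, "gain"), 1e-10)

  lapser <- agent_params(0.65, 0.95, subjective_ip = 5, choice_slope = 50,
                         lapse = 0.1)
  expect_equal(choice_probability(lapser, 1, "gain"), 0.05,
               tolerance = 1e-6)
})

test_that("probabilities increase in the offer and decrease in the shift", {
  base <- agent_params(0.65, 0.95, subjective_ip = 5, choice_slope = 1.2)
  p <- choice_probability(base, 1:9, "gain")
  expect_true(all(diff(p) > 0))
  for (offer in 1:9) {
    shifts <- c(0, 0.5, 1, 2)
    probs <- vapply(shifts, function(s) {
      a <- agent_params(0.65, 0.95, subjective_ip = 5, framing_shift = s,
                        choice_slope = 1.2)
      choice_probability(a, offer, "loss")
    }, numeric(1))
    expect_true(all(diff(probs) < 0))
  }
})

test_that("confidence reports return the stored percent, noisy draws stay bounded", {
  a <- agent_params(0.65, 0.95, conf_internal = 60, conf_external = 85,
                    subjective_ip = 5)
  expect_equal(report_confidence(a, "internal"), 60)
  expect_equal(report_confidence(a, "external"), 85)
  set.seed(6)
  draws <- replicate(10000, report_confidence(a, "internal", noise_sd = 5))
  expect_equal(mean(draws), 60, tolerance = 0.2)
  expect_true(all(draws >= 0 & draws <= 100))
})

test_that("population specs load from JSON and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_agents = 10, p_internal_mean = 0.7), path,
                       auto_unbox = TRUE)
  spec <- population_spec_from_json(path)
  expect_equal(spec$n_agents, 10)
  expect_equal(spec$p_internal_mean, 0.7)

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_agents = 10, bogus = 1), bad, auto_unbox = TRUE)
  expect_error(population_spec_from_json(bad), "unknown population spec")
})

test_that("population mean metacognitive bias matches its construction", {
  set.seed(7)
  pop <- sample_population(population_spec(2000))
  bias <- mean(pop$conf_internal) - 100 * mean(pop$p_internal)
  # offset -7 with symmetric reporting noise, mildly distorted by clamping
  expect_equal(bias, -7, tolerance = 1)
})
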