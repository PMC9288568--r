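#' Parameters of one synthetic participant
#'
#' An agent is a generative description of one participant in the optimal
#' reminders task: how well they remember targets internally and with
#' reminders, what accuracy they predict for themselves (metacognitive
#' confidence, on a 0-100 percent scale), and how they choose between the
#' two strategies on free-choice trials. Choice follows a lapse-augmented
#' logistic in the gain-equivalent offer, centred on the agent's subjective
#' indifference point; under loss framing the centre shifts by
#' `framing_shift` points (a positive shift means fewer reminder choices
#' when reminders are framed as losses).
#'
#' @param p_internal Probability of remembering a target with internal
#'   memory.
#' @param p_external Probability with reminders; must be at least 0.8 (the
#'   practice phase of the task gates participants at 8/10 correct with
#'   reminders, so sampled agents are past that gate).
#' @param conf_internal,conf_external Predicted accuracy in percent (0-100).
#' @param subjective_ip Offer value (gain-equivalent scale) at which the
#'   agent is indifferent between strategies under gain framing.
#' @param framing_shift Additive shift (points) of the indifference point
#'   under loss framing.
#' @param choice_slope Steepness of the choice sigmoid, per point; > 0.
#' @param lapse Probability of a uniformly random choice, in [0, 0.5].
#' @param offer_bounds Legal range for `subjective_ip` (default 1..9).
#' @return An object of class `agent_params`.
#' @export
#' @examples
#' agent_params(p_internal = 0.65, p_external = 0.95, subjective_ip = 5.5)
agent_params <- function(p_internal, p_external,
                         conf_internal = 100 * p_internal,
                         conf_external = 100 * p_external,
                         subjective_ip, framing_shift = 0,
                         choice_slope = 1.5, lapse = 0,
                         offer_bounds = c(1, 9)) {
  a <- list(p_internal = p_internal, p_external = p_external,
            conf_internal = conf_internal, conf_external = conf_external,
            subjective_ip = subjective_ip, framing_shift = framing_shift,
            choice_slope = choice_slope, lapse = lapse)
  stopifnot(
    p_internal >= 0, p_internal <= 1,
    p_external >= 0.8, p_external <= 1,
    conf_internal >= 0, conf_internal <= 100,
    conf_external >= 0, conf_external <= 100,
    subjective_ip >= offer_bounds[1], subjective_ip <= offer_bounds[2],
    choice_slope > 0,
    lapse >= 0, lapse <= 0.5
  )
  class(a) <- "agent_params"
  a
}

#' Coerce one row of a sampled population to `agent_params`
#'
#' @param row A one-row data frame with the columns of [sample_population()].
#' @param offer_bounds Legal offer range for the experiment.
#' @return An `agent_params` object.
#' @export
as_agent_params <- function(row, offer_bounds = c(1, 9)) {
  agent_params(p_internal = row$p_internal, p_external = row$p_external,
               conf_internal = row$conf_internal,
               conf_external = row$conf_external,
               subjective_ip = row$subjective_ip,
               framing_shift = row$framing_shift,
               choice_slope = row$choice_slope, lapse = row$lapse,
               offer_bounds = offer_bounds)
}

#' Population specification for sampling synthetic cohorts
#'
#' Describes the distributions from which [sample_population()] draws
#' agents. Defaults are calibrated so a simulated cohort lands near the
#' group-level behavior typical of the optimal reminders task: internal
#' accuracy around two-thirds, reminder accuracy near ceiling, mild
#' metacognitive underconfidence, a subjective indifference point about
#' 1.5 points below the normatively optimal one (producing a positive
#' reminder bias), and a loss-framing shift of about one point.
#'
#' @param n_agents Number of agents to draw.
#' @param experiment 1 or 2; sets the offer range the indifference point is
#'   truncated to.
#' @param p_internal_mean,p_internal_sd Truncated-normal parameters for
#'   internal accuracy (truncated to [0.05, 0.98]).
#' @param p_external_mean,p_external_sd Truncated normal for reminder
#'   accuracy, truncated to [0.8, 1].
#' @param conf_internal_offset,conf_external_offset Mean confidence minus
#'   100 x true accuracy, in percentage points (negative = underconfident).
#' @param conf_noise_sd Reporting noise around the confidence means.
#' @param ip_offset Mean of `subjective_ip` minus the agent's own optimal
#'   indifference point (negative = biased toward reminders).
#' @param ip_noise_sd Spread of `subjective_ip` around that mean.
#' @param framing_shift_mean,framing_shift_sd Truncated normal (min 0) for
#'   the loss-framing shift.
#' @param slope_meanlog,slope_sdlog Log-normal parameters of the choice
#'   slope.
#' @param lapse_shape1,lapse_shape2 Beta parameters of the lapse rate
#'   (rescaled to [0, 0.5]).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_agents,
                            experiment = 1,
                            p_internal_mean = 0.65, p_internal_sd = 0.12,
                            p_external_mean = 0.95, p_external_sd = 0.04,
                            conf_internal_offset = -7,
                            conf_external_offset = -11,
                            conf_noise_sd = 8,
                            ip_offset = -1.5, ip_noise_sd = 1.0,
                            framing_shift_mean = 1.0,
                            framing_shift_sd = 0.8,
                            slope_meanlog = log(1.5), slope_sdlog = 0.3,
                            lapse_shape1 = 1, lapse_shape2 = 19) {
  stopifnot(n_agents > 0, experiment %in% c(1, 2))
  spec <- as.list(environment())
  class(spec) <- "population_spec"
  spec
}

#' Read a population specification from JSON
#'
#' The document holds name/value pairs for [population_spec()] arguments
#' (`n_agents` mandatory); unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return A `population_spec` object.
#' @export
population_spec_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  legal <- names(formals(population_spec))
  extra <- setdiff(names(raw), legal)
  if (length(extra) > 0) {
    stop("unknown population spec keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(population_spec, raw)
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi <= plo) stop("infeasible truncation bounds", call. = FALSE)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Sample a population of synthetic participants
#'
#' Draws `n_agents` agents from a [population_spec()]. Confidence is
#' generated around `100 * accuracy + offset` and clamped to [0, 100];
#' the subjective indifference point is generated around each agent's own
#' optimal indifference point plus `ip_offset` and truncated to the offer
#' range. Uses the current RNG state; seed with [set.seed()] for
#' reproducibility.
#'
#' @param spec A [population_spec()].
#' @return A data frame with one row per agent and one column per
#'   parameter, plus `agent_id`.
#' @export
#' @examples
#' set.seed(11)
#' pop <- sample_population(population_spec(5))
#' pop[, c("p_internal", "p_external", "subjective_ip")]
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_agents
  bounds <- if (spec$experiment == 1) c(1, 9) else c(2, 8)

  p_int <- rtruncnorm(n, spec$p_internal_mean, spec$p_internal_sd,
                      0.05, 0.98)
  p_ext <- rtruncnorm(n, spec$p_external_mean, spec$p_external_sd,
                      0.8, 1)
  p_ext <- pmax(p_ext, p_int)  # reminders never worse than memory

  conf_int <- clamp(100 * p_int + spec$conf_internal_offset +
                      stats::rnorm(n, 0, spec$conf_noise_sd), 0, 100)
  conf_ext <- clamp(100 * p_ext + spec$conf_external_offset +
                      stats::rnorm(n, 0, spec$conf_noise_sd), 0, 100)

  oip <- clamp(10 * p_int / p_ext, bounds[1], bounds[2])
  sip <- clamp(oip + spec$ip_offset + stats::rnorm(n, 0, spec$ip_noise_sd),
               bounds[1], bounds[2])

  shift <- rtruncnorm(n, spec$framing_shift_mean, spec$framing_shift_sd,
                      0, Inf)
  slope <- stats::rlnorm(n, spec$slope_meanlog, spec$slope_sdlog)
  lapse <- 0.5 * stats::rbeta(n, spec$lapse_shape1, spec$lapse_shape2)

  data.frame(agent_id = seq_len(n), p_internal = p_int, p_external = p_ext,
             conf_internal = conf_int, conf_external = conf_ext,
             subjective_ip = sip, framing_shift = shift,
             choice_slope = slope, lapse = lapse)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Probability that an agent chooses reminders
#'
#' A lapse-augmented logistic in the gain-equivalent offer value:
#' `lapse/2 + (1 - lapse) * plogis(slope * (offer - s_f))`, where `s_f` is
#' the subjective indifference point, shifted by `framing_shift` under loss
#' framing. Strictly increasing in the offer.
#'
#' @param agent An [agent_params()] object (or population row).
#' @param offer_equiv Offer in gain-equivalent points (vectorized).
#' @param framing `"gain"` or `"loss"`.
#' @return Probability of choosing the external (reminder) strategy.
#' @export
#' @examples
#' a <- agent_params(0.65, 0.95, subjective_ip = 5, framing_shift = 1)
#' choice_probability(a, 5, "gain")   # 0.5 at the indifference point
#' choice_probability(a, 5, "loss")   # below 0.5: centre shifted to 6
choice_probability <- function(agent, offer_equiv, framing) {
  framing <- match.arg(framing, c("gain", "loss"))
  s_f <- agent$subjective_ip + agent$framing_shift * (framing == "loss")
  agent$lapse / 2 +
    (1 - agent$lapse) * stats::plogis(agent$choice_slope * (offer_equiv - s_f))
}

#' Report an agent's metacognitive confidence
#'
#' Returns the agent's predicted accuracy (percent) for the requested
#' strategy, optionally with Gaussian reporting noise clamped to [0, 100].
#' Mirrors the one-off confidence judgment made after the practice trials.
#'
#' @param agent An [agent_params()] object.
#' @param strategy `"internal"` or `"external"`.
#' @param noise_sd Reporting noise standard deviation (default 0: the
#'   stored value is returned as is).
#' @return Confidence in percent, in [0, 100].
#' @export
report_confidence <- function(agent, strategy, noise_sd = 0) {
  strategy <- match.arg(strategy, c("internal", "external"))
  conf <- if (strategy == "internal") agent$conf_internal else agent$conf_external
  if (noise_sd > 0) conf <- clamp(conf + stats::rnorm(1, 0, noise_sd), 0, 100)
  conf
}
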