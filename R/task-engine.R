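#' Task configuration for the optimal reminders task
#'
#' Builds the configuration of one experiment variant of the optimal
#' reminders task: 25 circles are dragged in sequence, 10 of them are
#' "special" (targets carrying a delayed intention), and targets occupy
#' positions 7 to 25 (the first 6 circles are on screen from the start and
#' cannot be targets). In experiment 1 a session has 17 trials (9 free-choice
#' with reminder offers 1 to 9, 8 forced); in experiment 2 each framing block
#' has 13 trials (7 free-choice with offers 2 to 8, 6 forced).
#'
#' @param experiment Integer, 1 or 2.
#' @return An object of class `task_config`: a list with fields
#'   `experiment`, `circles_total`, `visible_concurrent`, `n_targets`,
#'   `target_position_range` (inclusive integer bounds), `offer_values`,
#'   `trials_total` (per session for experiment 1, per block for
#'   experiment 2), and `full_reward` (points per target remembered with
#'   internal memory).
#' @export
#' @examples
#' task_config(1)
#' task_config(2)$offer_values
task_config <- function(experiment) {
  if (!experiment %in% c(1L, 2L)) {
    stop("`experiment` must be 1 or 2", call. = FALSE)
  }
  experiment <- as.integer(experiment)
  cfg <- list(
    experiment = experiment,
    circles_total = 25L,
    visible_concurrent = 6L,
    n_targets = 10L,
    target_position_range = c(7L, 25L),
    offer_values = if (experiment == 1L) 1:9 else 2:8,
    trials_total = if (experiment == 1L) 17L else 13L,
    full_reward = 10L
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  span <- cfg$target_position_range[2] - cfg$target_position_range[1] + 1L
  if (span != 2L * cfg$n_targets - 1L) {
    stop("target position range must span ", 2L * cfg$n_targets - 1L,
         " positions (got ", span, ")", call. = FALSE)
  }
  n_choice <- length(cfg$offer_values)
  if (cfg$trials_total != 2L * n_choice - 1L) {
    stop("trials_total must equal choice trials (", n_choice,
         ") + forced trials (", n_choice - 1L, ")", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a task configuration from JSON
#'
#' The JSON document must contain only fields of [task_config()]; unknown
#' keys are rejected rather than silently dropped.
#'
#' @param path Path to a JSON file.
#' @return A `task_config` object.
#' @export
task_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$experiment)) stop("JSON config lacks `experiment`", call. = FALSE)
  cfg <- task_config(raw$experiment)
  known <- names(cfg)
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  for (k in setdiff(names(raw), "experiment")) {
    cfg[[k]] <- if (is.numeric(raw[[k]])) as.integer(raw[[k]]) else raw[[k]]
  }
  validate_task_config(cfg)
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("Optimal reminders task, experiment", x$experiment, "\n")
  cat("  circles:", x$circles_total, " targets:", x$n_targets,
      " target positions:", x$target_position_range[1], "-",
      x$target_position_range[2], "\n")
  cat("  offers:", paste(x$offer_values, collapse = " "),
      " trials per", if (x$experiment == 1) "session:" else "block:",
      x$trials_total, "\n")
  invisible(x)
}

#' Draw target positions for one trial
#'
#' The 19 eligible sequence positions are partitioned into 10 adjacent bins:
#' nine bins of length two and one bin of length one, the short bin's slot
#' drawn uniformly among the ten. One target is then drawn uniformly within
#' each bin, so every trial has exactly one target per bin and ten targets
#' overall. Uses the current RNG state.
#'
#' @param config A [task_config()] object.
#' @return Sorted integer vector of 10 distinct positions in 7..25.
#' @export
#' @examples
#' set.seed(1)
#' generate_target_positions(task_config(1))
generate_target_positions <- function(config) {
  lo <- config$target_position_range[1]
  hi <- config$target_position_range[2]
  n_bins <- config$n_targets
  if (hi - lo + 1L != 2L * n_bins - 1L) {
    stop("target position range must have exactly ", 2L * n_bins - 1L,
         " positions", call. = FALSE)
  }
  short_bin <- sample.int(n_bins, 1L)
  lengths <- rep(2L, n_bins)
  lengths[short_bin] <- 1L
  ends <- lo - 1L + cumsum(lengths)
  starts <- ends - lengths + 1L
  # one uniform draw inside each bin
  offsets <- as.integer(floor(stats::runif(n_bins) * lengths))
  starts + offsets
}

#' Build the trial schedule of one session
#'
#' Odd-numbered trials are free-choice trials whose reminder offers are a
#' random permutation of the experiment's offer values (shown in the raw
#' units of the framing condition); even-numbered trials alternate
#' forced-external and forced-internal, with the starting forced type drawn
#' uniformly (or fixed via `forced_start`). Experiment 1 yields one 17-trial
#' session in a single framing; experiment 2 yields two 13-trial blocks, one
#' per framing, in the order given.
#'
#' Raw offers: gain framing shows the offer itself; experiment 1 loss
#' framing shows minus points (offer - 10, i.e. -9..-1); experiment 2 loss
#' framing shows points lost (10 - offer, i.e. 2..8).
#'
#' @param experiment 1 or 2.
#' @param framing_assignment For experiment 1 a single framing, `"gain"` or
#'   `"loss"`. For experiment 2 the block order, e.g. `c("gain", "loss")`.
#' @param forced_start Optional: `"external"` or `"internal"` to fix the
#'   first forced-trial type instead of randomizing it. For experiment 2 a
#'   length-2 vector (one per block) is accepted.
#' @return A data frame with one row per trial: `block`, `trial_index`
#'   (1-based within block), `trial_type` (`choice`, `forced_internal`,
#'   `forced_external`), `framing`, `offer_raw` (NA on forced trials),
#'   `offer_equiv` (gain-equivalent points, NA on forced trials), and
#'   `target_positions` (semicolon-joined).
#' @export
#' @examples
#' set.seed(7)
#' plan <- build_session_plan(1, "gain")
#' table(plan$trial_type)
build_session_plan <- function(experiment, framing_assignment,
                               forced_start = NULL) {
  if (!experiment %in% c(1L, 2L)) stop("invalid experiment id", call. = FALSE)
  cfg <- task_config(experiment)
  framings <- match.arg(framing_assignment, c("gain", "loss"),
                        several.ok = TRUE)
  if (experiment == 1L && length(framings) != 1L) {
    stop("experiment 1 assigns a single framing per participant", call. = FALSE)
  }
  if (experiment == 2L && length(framings) != 2L) {
    stop("experiment 2 needs a block order over both framings", call. = FALSE)
  }
  if (is.null(forced_start)) {
    forced_start <- sample(c("external", "internal"),
                           length(framings), replace = TRUE)
  } else {
    forced_start <- rep(match.arg(forced_start, c("external", "internal"),
                                  several.ok = TRUE),
                        length.out = length(framings))
  }
  blocks <- lapply(seq_along(framings), function(b) {
    build_block(cfg, framings[b], b, forced_start[b])
  })
  do.call(rbind, blocks)
}

build_block <- function(cfg, framing, block, forced_start) {
  n_trials <- cfg$trials_total
  n_choice <- length(cfg$offer_values)
  trial_type <- character(n_trials)
  trial_type[seq(1L, n_trials, by = 2L)] <- "choice"
  forced_types <- if (forced_start == "external") {
    c("forced_external", "forced_internal")
  } else {
    c("forced_internal", "forced_external")
  }
  even <- seq(2L, n_trials, by = 2L)
  trial_type[even] <- rep_len(forced_types, length(even))

  offer_equiv <- rep(NA_real_, n_trials)
  offer_equiv[trial_type == "choice"] <- sample(cfg$offer_values)
  offer_raw <- vapply(offer_equiv, function(v) {
    if (is.na(v)) NA_real_ else raw_offer_value(v, framing, cfg$experiment)
  }, numeric(1))

  targets <- vapply(seq_len(n_trials), function(i) {
    paste(generate_target_positions(cfg), collapse = ";")
  }, character(1))

  data.frame(
    block = block,
    trial_index = seq_len(n_trials),
    trial_type = trial_type,
    framing = framing,
    offer_raw = offer_raw,
    offer_equiv = offer_equiv,
    target_positions = targets,
    stringsAsFactors = FALSE
  )
}

# inverse of equivalent_gain_value: what the participant is shown
raw_offer_value <- function(offer_equiv, framing, experiment) {
  if (framing == "gain") return(offer_equiv)
  if (experiment == 1L) offer_equiv - 10 else 10 - offer_equiv
}

#' Simulate the outcomes of one trial
#'
#' Each of the trial's targets is remembered independently with probability
#' `p_internal` (internal strategy) or `p_external` (reminders). For choice
#' trials the strategy must already be resolved (see
#' [simulate_session()] for the full agent loop).
#'
#' @param agent An [agent_params()] object (or one row of a sampled
#'   population coerced with [as_agent_params()]).
#' @param strategy `"internal"` or `"external"`.
#' @param n_targets Number of targets on the trial (default 10).
#' @return A list with `strategy_used`, `outcomes` (logical hit vector) and
#'   `n_hits`.
#' @export
simulate_trial <- function(agent, strategy, n_targets = 10L) {
  strategy <- match.arg(strategy, c("internal", "external"))
  p <- if (strategy == "internal") agent$p_internal else agent$p_external
  if (p < 0 || p > 1) stop("hit probability outside [0, 1]", call. = FALSE)
  outcomes <- stats::runif(n_targets) < p
  list(strategy_used = strategy, outcomes = outcomes,
       n_hits = sum(outcomes))
}

#' Simulate a full session for one agent
#'
#' Walks a session plan trial by trial: forced trials use the imposed
#' strategy; on choice trials the agent picks reminders with probability
#' [choice_probability()] evaluated at the trial's gain-equivalent offer.
#' Target-level memory success is Bernoulli per target.
#'
#' @param agent An [agent_params()] object.
#' @param plan A session plan from [build_session_plan()].
#' @return The plan with columns `strategy_used` and `n_hits` appended.
#' @export
#' @examples
#' set.seed(2)
#' a <- agent_params(p_internal = 0.65, p_external = 0.95,
#'                   subjective_ip = 5, choice_slope = 2)
#' sess <- simulate_session(a, build_session_plan(1, "gain"))
#' mean(sess$n_hits[sess$trial_type == "forced_internal"]) / 10
simulate_session <- function(agent, plan) {
  n <- nrow(plan)
  strategy <- character(n)
  n_hits <- integer(n)
  for (i in seq_len(n)) {
    type <- plan$trial_type[i]
    strategy[i] <- switch(type,
      forced_internal = "internal",
      forced_external = "external",
      choice = {
        p_rem <- choice_probability(agent, plan$offer_equiv[i],
                                    plan$framing[i])
        if (stats::runif(1) < p_rem) "external" else "internal"
      }
    )
    p_hit <- if (strategy[i] == "internal") agent$p_internal else agent$p_external
    n_hits[i] <- stats::rbinom(1L, 10L, p_hit)
  }
  plan$strategy_used <- strategy
  plan$n_hits <- n_hits
  plan
}
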