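#' Point-biserial correlation between offers and strategy choices
#'
#' Pearson correlation of the offered reminder value with the binary
#' strategy choice (1 = reminders). A participant choosing at random, or
#' perversely setting more reminders when they pay less, yields a
#' non-positive correlation. When either vector is constant the
#' correlation is undefined and `NA` is returned (flagged, never treated
#' as negative).
#'
#' @param offers Offer values.
#' @param choices Binary choices (0/1).
#' @return Correlation coefficient, or `NA` if undefined.
#' @export
#' @examples
#' point_biserial(1:9, as.integer(1:9 >= 5))  # strongly positive
point_biserial <- function(offers, choices) {
  if (length(offers) != length(choices)) {
    stop("offers and choices differ in length", call. = FALSE)
  }
  stopifnot(length(offers) >= 2, all(choices %in% c(0, 1)))
  if (stats::sd(offers) == 0 || stats::sd(choices) == 0) return(NA_real_)
  stats::cor(offers, choices)
}

# deterministic accuracy/choice rules shared by both experiments:
# (a) mean internal accuracy < 10%; (b) mean external accuracy < 70%;
# (c) internal > external in any single condition; (d) negative
# point-biserial offer/choice correlation
deterministic_rules <- function(measures, trials) {
  pids <- unique(measures$participant_id)
  out <- lapply(pids, function(pid) {
    m <- measures[measures$participant_id == pid, ]
    ch <- trials[trials$participant_id == pid &
                   trials$trial_type == "choice", ]
    rpb <- point_biserial(ch$offer_equiv,
                          as.integer(ch$strategy_used == "external"))
    reasons <- character(0)
    if (mean(m$acc_fi) < 0.10) reasons <- c(reasons, "a")
    if (mean(m$acc_fe) < 0.70) reasons <- c(reasons, "b")
    if (any(m$acc_fi > m$acc_fe)) reasons <- c(reasons, "c")
    if (!is.na(rpb) && rpb < 0) reasons <- c(reasons, "d")
    data.frame(participant_id = pid,
               mean_acc_fi = mean(m$acc_fi), mean_acc_fe = mean(m$acc_fe),
               point_biserial = rpb,
               reasons = paste(reasons, collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

finalize_reports <- function(rep) {
  rep$excluded <- nchar(rep$reasons) > 0
  rownames(rep) <- NULL
  rep
}

#' Exclusion screen for the between-participants design
#'
#' Applies the preregistration-style rules in order: (a) mean
#' forced-internal accuracy below 10 percent; (b) mean forced-external
#' accuracy below 70 percent; (c) internal accuracy exceeding external in
#' any condition; (d) negative point-biserial correlation between offers
#' and strategy choice; (e) reminder bias more than `sd_threshold`
#' standard deviations from the group mean, with the group mean and SD
#' computed over participants surviving (a)-(d) (configurable).
#'
#' @param measures Per-participant measures from [compute_measures()].
#' @param trials The cohort trial table the measures came from.
#' @param sd_threshold Threshold in SD units for rule (e); default 2.5.
#' @param stats_on_survivors Compute the rule-(e) group statistics on
#'   participants surviving (a)-(d) (default) rather than on everyone.
#' @return A data frame of exclusion reports: one row per participant with
#'   `excluded`, `reasons` (a compact string of reason codes), and the
#'   diagnostics behind each rule (mean accuracies, point-biserial r,
#'   deviation of the bias in SD units).
#' @export
apply_exclusions_exp1 <- function(measures, trials, sd_threshold = 2.5,
                                  stats_on_survivors = TRUE) {
  if (nrow(measures) == 0) stop("empty cohort", call. = FALSE)
  rep <- deterministic_rules(measures, trials)

  bias <- tapply(measures$reminder_bias, measures$participant_id, mean)
  bias <- bias[as.character(rep$participant_id)]
  # group statistics from the post-(a-d) survivors; deviations evaluated
  # for everyone so independent rules can co-occur on one participant
  base <- if (stats_on_survivors) rep$reasons == "" else rep(TRUE, nrow(rep))
  mu <- mean(bias[base]); sdev <- stats::sd(bias[base])
  dev <- if (is.na(sdev) || sdev == 0) rep(0, nrow(rep)) else abs(bias - mu) / sdev
  rep$mean_bias <- as.numeric(bias)
  rep$bias_sd_units <- as.numeric(dev)
  flag_e <- dev > sd_threshold
  rep$reasons[flag_e] <- paste0(rep$reasons[flag_e], "e")
  finalize_reports(rep)
}

#' Scaled median absolute deviation units from the median
#'
#' Deviation of each value from the sample median, in units of the median
#' absolute deviation scaled by the normal-consistency constant 1.4826
#' (the robust-screening convention; set `constant = 1` for raw MAD).
#'
#' @param x Numeric vector.
#' @param constant Consistency constant (default 1.4826).
#' @return Nonnegative deviations, same length as `x`.
#' @export
#' @examples
#' mad_units(c(1, 2, 3, 4, 100))[5]  # about 65.4
mad_units <- function(x, constant = 1.4826) {
  med <- stats::median(x)
  m <- stats::median(abs(x - med)) * constant
  if (m == 0) return(ifelse(x == med, 0, Inf))
  abs(x - med) / m
}

#' Exclusion screen for the within-participants design
#'
#' Rules (a)-(d) as in [apply_exclusions_exp1()], with accuracies averaged
#' across the gain and loss conditions and the offer/choice correlation
#' computed on the pooled choice trials of both blocks (gain-equivalent
#' offers). Three robust outlier rules follow, each at
#' `mad_threshold` scaled-MAD units (see [mad_units()]) computed over
#' participants surviving (a)-(d): (e) the reminder bias averaged across
#' framings; (f) the gain-minus-loss difference in reminder bias; (g) the
#' internal metacognitive bias.
#'
#' @param measures Per-participant measures (both framings per
#'   participant, with `metacog_internal_bias`).
#' @param trials Cohort trial table.
#' @param mad_threshold Threshold in scaled-MAD units; default 3.
#' @param mad_constant Consistency constant for the MAD (default 1.4826).
#' @return Exclusion reports as in [apply_exclusions_exp1()], with
#'   diagnostics `mean_bias`, `bias_diff`, `metacog_internal_bias` and
#'   their deviations in MAD units.
#' @export
apply_exclusions_exp2 <- function(measures, trials, mad_threshold = 3,
                                  mad_constant = 1.4826) {
  if (nrow(measures) == 0) stop("empty cohort", call. = FALSE)
  pids <- unique(measures$participant_id)
  both <- tapply(measures$framing, measures$participant_id,
                 function(f) all(c("gain", "loss") %in% f))
  if (!all(both)) stop("every participant needs both framing conditions",
                       call. = FALSE)
  if (!"metacog_internal_bias" %in% names(measures)) {
    stop("measures lack `metacog_internal_bias`", call. = FALSE)
  }
  rep <- deterministic_rules(measures, trials)

  per <- function(col, fun) {
    v <- vapply(rep$participant_id, function(pid) {
      m <- measures[measures$participant_id == pid, ]
      fun(m)
    }, numeric(1))
    v
  }
  rep$mean_bias <- per("bias", function(m) mean(m$reminder_bias))
  rep$bias_diff <- per("diff", function(m) {
    m$reminder_bias[m$framing == "gain"] - m$reminder_bias[m$framing == "loss"]
  })
  rep$metacog_internal_bias <- per("mcb", function(m) m$metacog_internal_bias[1])

  # median and MAD from the post-(a-d) survivors; deviations evaluated for
  # everyone so independent rules can co-occur on one participant
  base <- rep$reasons == ""
  robust <- list(e = "mean_bias", f = "bias_diff", g = "metacog_internal_bias")
  for (code in names(robust)) {
    x <- rep[[robust[[code]]]]
    med <- stats::median(x[base])
    m <- stats::median(abs(x[base] - med)) * mad_constant
    units <- if (m == 0) ifelse(x == med, 0, Inf) else abs(x - med) / m
    rep[[paste0(robust[[code]], "_mad_units")]] <- units
    flag <- units > mad_threshold
    rep$reasons[flag] <- paste0(rep$reasons[flag], code)
  }
  finalize_reports(rep)
}
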