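#' Forced-trial accuracy
#'
#' Mean target accuracy — total hits over total targets — across the forced
#' trials of one type in a simulated (or imported) session table.
#'
#' @param session A session data frame with columns `trial_type` and
#'   `n_hits` (see [simulate_session()]).
#' @param trial_type `"forced_internal"` or `"forced_external"`.
#' @param n_targets Targets per trial (default 10).
#' @return Proportion in [0, 1].
#' @export
accuracy <- function(session, trial_type, n_targets = 10L) {
  trial_type <- match.arg(trial_type, c("forced_internal", "forced_external"))
  rows <- session$trial_type == trial_type
  if (!any(rows)) stop("no trials of type ", trial_type, call. = FALSE)
  sum(session$n_hits[rows]) / (n_targets * sum(rows))
}

#' Gain-equivalent value of a displayed offer
#'
#' Free-choice offers are displayed in the units of the framing condition;
#' indifference points are estimated on a common gain-equivalent scale.
#' Gain framing is the identity. In experiment 1, loss offers are minus
#' points (-9..-1) and the equivalent adds 10. In experiment 2, loss offers
#' are points lost (2..8) and the equivalent is 10 minus the offer (losing
#' 3 of the 10 available points retains 7).
#'
#' @param offer_raw Displayed offer (vectorized).
#' @param framing `"gain"` or `"loss"`.
#' @param experiment 1 or 2.
#' @return Gain-equivalent points.
#' @export
#' @examples
#' equivalent_gain_value(-9, "loss", 1)  # 1
#' equivalent_gain_value(3, "loss", 2)   # 7
equivalent_gain_value <- function(offer_raw, framing, experiment) {
  framing <- match.arg(framing, c("gain", "loss"))
  stopifnot(experiment %in% c(1, 2))
  rng <- if (experiment == 1) 1:9 else 2:8
  legal <- if (framing == "gain") rng else if (experiment == 1) rng - 10 else rng
  if (any(!offer_raw %in% legal)) {
    stop("raw offer out of range for this framing/experiment", call. = FALSE)
  }
  if (framing == "gain") offer_raw
  else if (experiment == 1) offer_raw + 10
  else 10 - offer_raw
}

#' Optimal indifference point
#'
#' The offer value at which an unbiased participant should be indifferent
#' between strategies, from the balance
#' `OIP x ACC_FE = full_reward x ACC_FI`: reminders pay off exactly when
#' the offer times reminder accuracy matches the full reward times internal
#' accuracy. Values outside the offer range are clamped to its bounds so
#' the OIP lives on the same scale as the estimable actual indifference
#' point.
#'
#' @param acc_fi Forced-internal accuracy, in [0, 1].
#' @param acc_fe Forced-external accuracy, in (0, 1]; must be at least
#'   `acc_fi`.
#' @param full_reward Points per target remembered with memory (default 10).
#' @param bounds Offer range, e.g. `c(1, 9)` or `c(2, 8)`.
#' @return OIP in points, clamped to `bounds`.
#' @export
#' @examples
#' compute_oip(0.55, 1.00)            # 5.5
#' compute_oip(0.90, 0.90)            # clamped to 9
compute_oip <- function(acc_fi, acc_fe, full_reward = 10, bounds = c(1, 9)) {
  stopifnot(all(acc_fi >= 0), all(acc_fi <= 1), all(acc_fe <= 1))
  if (any(acc_fe <= 0)) {
    stop("acc_fe = 0: the optimal indifference point is undefined",
         call. = FALSE)
  }
  clamp(full_reward * acc_fi / acc_fe, bounds[1], bounds[2])
}

#' Fit the actual indifference point (AIP)
#'
#' Maximum-likelihood fit of a two-parameter sigmoid (logistic by default)
#' to binary strategy choices over gain-equivalent offers, with choice
#' coded 1 = reminders and 0 = own memory. The AIP is the offer at which
#' the fitted curve crosses 50 percent, clamped to the offer range.
#'
#' Degenerate response patterns resolve to the bounds: a participant who
#' always chooses reminders is indifferent at or below the smallest offer
#' (AIP = lower bound), and mirror-wise for always-memory. With one
#' observation per offer, perfectly step-like data push the slope to its
#' cap (default 50 per point); the location is then the likelihood
#' maximizer at the cap, inside the step interval.
#'
#' In the (intercept, slope) parametrization the likelihood is a concave
#' logistic (or probit) regression, so the interior maximum is found
#' globally by iteratively reweighted least squares; boundary cases
#' (separable data, slopes at the cap or floor, locations far outside the
#' offer range) fall back to a one-dimensional profile of the location at
#' the boundary slope, which is again concave. Failure of the interior fit
#' is flagged in `converged` while the best boundary candidate is still
#' returned.
#'
#' @param offers Gain-equivalent offers.
#' @param choices Binary choices (1 = reminders).
#' @param bounds Offer range the AIP is clamped to.
#' @param link `"logistic"` (default) or `"probit"`.
#' @param slope_max Cap on the slope (per point).
#' @return An object of class `psychometric_fit`: a list with `aip`
#'   (clamped location), `location_raw`, `slope`, `log_likelihood`,
#'   `converged`, `n_choices`, `link`, `bounds`.
#' @export
#' @examples
#' fit_aip(1:9, as.integer(1:9 >= 6))$aip  # step between 5 and 6
fit_aip <- function(offers, choices, bounds = c(1, 9),
                    link = c("logistic", "probit"), slope_max = 50) {
  link <- match.arg(link)
  stopifnot(length(offers) == length(choices), length(choices) > 0,
            all(choices %in% c(0, 1)))
  cdf <- if (link == "logistic") stats::plogis else stats::pnorm

  out <- list(link = link, bounds = bounds, n_choices = length(choices))

  if (all(choices == 1) || all(choices == 0)) {
    loc <- if (all(choices == 1)) bounds[1] else bounds[2]
    out <- c(out, list(aip = loc, location_raw = loc, slope = slope_max,
                       log_likelihood = 0, converged = TRUE))
    class(out) <- "psychometric_fit"
    return(out)
  }

  # box for the raw location: a little beyond the offer range so clamping,
  # not the optimizer box, decides boundary cases
  loc_box <- c(bounds[1] - 2, bounds[2] + 2)
  ll <- function(loc, slope) {
    p <- cdf(slope * (offers - loc))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(choices * log(p) + (1 - choices) * log1p(-p))
  }
  # profile over location at a fixed slope; the log-likelihood is concave
  # in the intercept, hence in the location, so optimize() is global
  profile_loc <- function(slope) {
    opt <- stats::optimize(function(l) ll(l, slope), loc_box, maximum = TRUE)
    list(loc = opt$maximum, slope = slope, ll = opt$objective,
         converged = TRUE)
  }

  # the MLE in (intercept, slope) is a concave logistic/probit regression:
  # glm finds the global optimum when it exists in the interior
  fam <- if (link == "logistic") stats::binomial("logit")
         else stats::binomial("probit")
  glm_fit <- withCallingHandlers(
    tryCatch(stats::glm.fit(cbind(1, offers), choices, family = fam),
             error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning"))

  res <- NULL
  if (!is.null(glm_fit) && all(is.finite(glm_fit$coefficients))) {
    b <- glm_fit$coefficients
    slope_hat <- unname(b[2])
    if (glm_fit$converged && slope_hat > 1e-3 && slope_hat < slope_max) {
      loc_hat <- unname(-b[1] / b[2])
      if (loc_hat >= loc_box[1] && loc_hat <= loc_box[2]) {
        res <- list(loc = loc_hat, slope = slope_hat,
                    ll = ll(loc_hat, slope_hat), converged = TRUE)
      }
    }
  }
  if (is.null(res)) {
    # boundary cases (separable data, runaway location, negative trend):
    # profile the location at the capped and at a near-flat slope
    cands <- list(profile_loc(slope_max), profile_loc(1e-3))
    res <- cands[[which.max(vapply(cands, `[[`, numeric(1), "ll"))]]
    res$converged <- !is.null(glm_fit)
  }
  out <- c(out, list(
    aip = clamp(res$loc, bounds[1], bounds[2]),
    location_raw = res$loc,
    slope = res$slope,
    log_likelihood = res$ll,
    converged = res$converged
  ))
  class(out) <- "psychometric_fit"
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit (%s): AIP = %.3f (raw %.3f), slope = %.3f\n",
              x$link, x$aip, x$location_raw, x$slope))
  cat(sprintf("  logLik = %.3f over %d choices; converged: %s\n",
              x$log_likelihood, x$n_choices, x$converged))
  invisible(x)
}

#' Reminder bias
#'
#' Optimal minus actual indifference point. Positive values mean the
#' participant switches to reminders at cheaper offers than is optimal
#' (overuse of reminders); negative values mean a bias toward internal
#' memory.
#'
#' @param oip,aip Indifference points on the same bounded scale.
#' @return Bias in points.
#' @export
reminder_bias <- function(oip, aip) oip - aip

#' Metacognitive bias
#'
#' Predicted accuracy (percent) minus actual accuracy, in percentage
#' points. Positive = overconfident, negative = underconfident.
#'
#' @param confidence_pct Confidence in [0, 100].
#' @param accuracy_prop Accuracy in [0, 1].
#' @return Bias in percentage points.
#' @export
#' @examples
#' metacognitive_bias(60, 0.65)  # -5: underconfident
metacognitive_bias <- function(confidence_pct, accuracy_prop) {
  confidence_pct - 100 * accuracy_prop
}

#' Per-participant measures from a cohort trial table
#'
#' Computes, per participant and framing condition: forced-internal and
#' forced-external accuracy, the optimal and actual indifference points,
#' the reminder bias, and (when confidence columns are present) the
#' internal and external metacognitive biases. Metacognitive confidence is
#' a single pre-task rating, so its bias is computed against forced-trial
#' accuracy pooled across framing conditions.
#'
#' @param trials Long trial table: columns `participant_id`, `experiment`,
#'   `framing`, `trial_type`, `offer_equiv`, `strategy_used`, `n_hits`, and
#'   optionally `conf_internal`, `conf_external` (constant within
#'   participant).
#' @param pool_metacog_accuracy Pool accuracy across framings for the
#'   metacognitive bias (default TRUE; set FALSE to use per-framing
#'   accuracy).
#' @return Data frame with one row per participant x framing:
#'   `participant_id`, `framing`, `acc_fi`, `acc_fe`, `oip`, `aip`,
#'   `reminder_bias`, `fit_converged`, and metacognitive biases when
#'   confidence was supplied.
#' @export
compute_measures <- function(trials, pool_metacog_accuracy = TRUE) {
  stopifnot(nrow(trials) > 0)
  experiment <- trials$experiment[1]
  bounds <- if (experiment == 1) c(1, 9) else c(2, 8)
  has_conf <- all(c("conf_internal", "conf_external") %in% names(trials))

  rows <- list()
  for (pid in unique(trials$participant_id)) {
    pt <- trials[trials$participant_id == pid, ]
    pooled_fi <- accuracy(pt, "forced_internal")
    pooled_fe <- accuracy(pt, "forced_external")
    for (fr in unique(pt$framing)) {
      ft <- pt[pt$framing == fr, ]
      acc_fi <- accuracy(ft, "forced_internal")
      acc_fe <- accuracy(ft, "forced_external")
      oip <- compute_oip(acc_fi, acc_fe, bounds = bounds)
      ch <- ft[ft$trial_type == "choice", ]
      fit <- fit_aip(ch$offer_equiv, as.integer(ch$strategy_used == "external"),
                     bounds = bounds)
      row <- data.frame(
        participant_id = pid, framing = fr,
        acc_fi = acc_fi, acc_fe = acc_fe,
        oip = oip, aip = fit$aip,
        reminder_bias = reminder_bias(oip, fit$aip),
        fit_converged = fit$converged,
        stringsAsFactors = FALSE
      )
      if (has_conf) {
        afi <- if (pool_metacog_accuracy) pooled_fi else acc_fi
        afe <- if (pool_metacog_accuracy) pooled_fe else acc_fe
        row$metacog_internal_bias <- metacognitive_bias(pt$conf_internal[1], afi)
        row$metacog_external_bias <- metacognitive_bias(pt$conf_external[1], afe)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
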