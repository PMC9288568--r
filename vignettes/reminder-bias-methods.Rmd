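---
title: "Simulating and analyzing optimal reminder use under framing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing optimal reminder use under framing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remindersim)
```

## The task and its measures

In the optimal reminders task a participant drags 25 numbered circles to
the bottom of a box in sequence. Ten of the circles are "special": they
appear briefly in a color that instructs a delayed intention (drag this
circle to the matching edge when its turn comes). Intentions can be held
in internal memory — worth the full reward of 10 points per remembered
target — or offloaded by setting a reminder, worth a smaller per-target
offer that varies across trials. Sessions alternate free-choice trials
with forced trials that impose one strategy, and the forced trials
calibrate each participant:

* `ACC_FI`, `ACC_FE` — mean target accuracy on forced-internal and
  forced-external trials.
* **OIP** (optimal indifference point) — the offer at which an unbiased
  participant should be indifferent, from
  `OIP × ACC_FE = 10 × ACC_FI`, clamped to the offer range.
* **AIP** (actual indifference point) — the 50% point of a sigmoid fitted
  to the binary strategy choices over offers.
* **Reminder bias** = OIP − AIP. Positive values mean reminders are used
  at offers where memory would pay more — the typical human result.

Framing enters by presenting the reminder offer as a gain or as a loss.
On the gain-equivalent scale both framings are scored identically, so any
AIP shift between framings is a pure preference (risk-attitude) effect.
The between-participants variant runs one 17-trial session per person
(9 choice offers 1–9, 8 forced); the within-participants variant runs two
13-trial blocks (7 choice offers 2–8, 6 forced), one per framing, with
block order counterbalanced by alternation over the participant index.
Loss offers convert to gain equivalents by adding 10 (between design,
where loss offers are −9…−1) or subtracting from 10 (within design,
where they are points lost, 2…8).

## The generative agent model

Each synthetic participant is a parameter vector: accuracies
`p_internal`, `p_external`; confidence reports `conf_internal`,
`conf_external` (percent); a subjective indifference point; a loss-framing
shift; a choice slope; and a lapse rate. Choice on a free trial is a
lapse-augmented logistic in the gain-equivalent offer,

`P(reminders) = lapse/2 + (1 − lapse) · logistic(slope · (offer − s_f))`,

with `s_f = subjective_ip + framing_shift` under loss framing. A positive
shift reproduces the headline effect — fewer reminders, hence a smaller
reminder bias, under loss framing — as an additive change in the
indifference point, the simplest mechanism consistent with a preference
shift without a preference reversal. Memory success is independent
Bernoulli per target; serial-position and load effects are deliberately
out of the model (the measures depend only on hit counts), and so are
learning, fatigue and effort costs.

Default population distributions (all truncated to their legal ranges):
`p_internal ~ N(0.65, 0.12)`, `p_external ~ N(0.95, 0.04)` bounded below
at 0.8 — the practice phase of the real task gates participants at 8/10
reminder accuracy, so the sampler enforces the same floor rather than
simulating practice. Confidence is generated around
`100·accuracy − 7` (internal) and `− 11` (external) with SD-8 reporting
noise, giving the mild group-level underconfidence typical of this task.
The subjective indifference point sits `1.5` points below each agent's
own OIP (SD 1), producing a positive reminder bias of roughly 1–2 points;
`framing_shift ~ N(1.0, 0.8)` truncated at 0; slope is log-normal around
1.5 per point; lapse is Beta(1, 19) rescaled to [0, 0.5]. Group means of
the task's published summaries constrain only the centres of these
distributions; the spreads are this package's calibration choices and are
flagged as such — cohorts simulated from them match group-level
statistics by construction, not individual-level variance structure, so
passing tests certify the estimators and pipeline, not distributional
realism of any human sample.

Target positions occupy the 19 eligible sequence slots (7–25) split into
ten adjacent bins — nine of length two, one of length one, the short
bin's slot uniform among the ten, one uniform draw per bin. "Placed
randomly" is resolved as uniform at both levels, the minimal assumption.
The first forced-trial type is drawn uniformly per participant
(per block in the within design).

## Estimating the AIP

The AIP fit is a two-parameter logistic (location, slope ≥ 0) maximized
by likelihood; a probit link is available as a switch. No lapse parameter
is estimated: with 7–9 binary observations per condition a three-parameter
fit is poorly identified, and the generative lapse is small. In the
(intercept, slope) parametrization the log-likelihood is concave, so the
interior optimum comes from logistic regression (IRLS) and is global;
boundary cases fall back to a one-dimensional concave profile of the
location at the slope cap (50 per point) or floor (0.001). All-reminders
and all-memory response patterns are resolved by the bounding rule —
lower and upper offer bound respectively — and every location estimate is
reported both raw and clamped to the offer range, the scale on which OIP
is also bounded.

Two numerical caveats are documented rather than hidden. First, with one
observation per offer, perfect steps drive the slope to its cap; the
location is then the profile-likelihood maximizer inside the step
interval (5.5 for a step between 5 and 6). Second, the two-parameter MLE
is not monotone in single choices everywhere: turning an isolated
lowest-offer choice to "reminders" amid mostly-memory responses can
*raise* the fitted location, because the likelihood prefers flattening
the slope. The brute-force grid oracle reproduces the same behavior, and
the test suite pins both the common-case monotonicity and this
counterexample.

## Exclusion screens

Both preregistration-style pipelines run deterministic rules first:
(a) mean internal accuracy < 10%; (b) mean reminder accuracy < 70%;
(c) internal above external accuracy in any condition; (d) a negative
point-biserial correlation between offer and choice. Constant choice
vectors leave (d) undefined; such participants are retained, since the
rule targets a negative correlation specifically. Distributional rules
are then applied once, non-iteratively, with group statistics taken from
the rule-(a–d) survivors: the between-design rule flags reminder-bias
scores beyond 2.5 SD of the group mean; the within-design rules flag the
framing-averaged bias, the gain–loss bias difference, and the internal
metacognitive bias beyond 3 scaled-MAD units (consistency constant
1.4826; a raw-MAD switch exists). Deviations are evaluated for every
participant against those group statistics, so a participant can carry
several reason codes at once, and each report records the diagnostics
that reproduce its decision.

## The inferential battery

The t tests, correlations and 2×2 ANOVAs are computed from their closed
forms, with the effect-size conventions used in this literature: d and
d_z as t/√n (no small-sample correction), partial η² as
SS_effect/(SS_effect + SS_error). For the balanced mixed design, the
between-factor F equals the squared two-sample t on subject means and the
interaction F the squared t on difference scores; the test suite enforces
both identities and agreement with `aov()` error strata to 1e-10.
Independent correlations are compared on the Fisher-z scale; dependent
non-overlapping correlations (two correlations on the same sample with no
shared variable) support both classical flavors — the raw-scale statistic
with the four-cross-correlation covariance term, and the same covariance
applied on the Fisher-z scale — selected by parameter, since both appear
in this literature without restated formulas. Mixed models are fitted by
maximum likelihood (never REML) through `lme4`, so AIC differences and
likelihood-ratio chi-squares satisfy χ² = ΔAIC + 2Δk exactly; p values
use the χ² reference with df = Δk. Power for the paired design uses the
noncentral t distribution directly, returning the smallest n whose power
reaches the target.

Sidedness is an explicit parameter everywhere (the bias-against-zero
tests were one-tailed in the between-participants study, two-tailed in
the within-participants one); the default is two-tailed.

## Pipeline and verification

`run_experiment()` chains the stages — sample, simulate, measure, screen,
analyze — under a mandatory seed; identical configurations reproduce
identical reports, and the emitted trial CSV re-analyzes to the same
measures. Framing assignment in the between design is simple
randomization (an equal-allocation switch exists); within-design block
order alternates deterministically by participant index and is recorded.

`verify_anchors()` recomputes the internally redundant quantities of the
reference framing studies — effect sizes from their t and n, the framing
effect from its two condition means, likelihood-ratio statistics from the
AIC sequence, the power-analysis n, the independent-correlations z —
through the package's own functions. Tolerances are matched to input
rounding: 0.005 for exact arithmetic on two-decimal inputs, 0.02 for the
AIC identities, 0.05 for the z statistic recomputed from two-decimal
correlations (the value from unrounded correlations differs in the second
decimal).

## Problem sizes and known limitations

The test suite validates estimator behavior at the study's own scale:
parameter recovery with 200 choices per offer over 200 agents
(tolerance ±0.15 points at 95% coverage), grid-oracle equivalence on 100
small datasets (location grid step 0.005), a 500-agent null cohort for
the unbiased-agent property (|mean bias| < 0.1), and 100 within-design
cohorts of n = 300 per framing-shift condition for effect recovery and
type-I control. Known limitations: no trial-level learning or effort
model; the generative choice model is the logistic the fit assumes, so
recovery tests do not probe link misspecification; and single-session
indifference-point estimates are noisy by design (9 or 14 binary choices),
which is the regime the screening rules exist for.
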