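# remindersim

People fulfil delayed intentions either from internal memory or by
offloading them onto external reminders, and they systematically offload
more than is optimal. `remindersim` is an R package for studying that
*reminder bias* and how gain/loss framing shifts it, by simulating the
**optimal reminders task** end to end: no human data are required.

In the task, forced trials measure accuracy with memory (`ACC_FI`) and
with reminders (`ACC_FE`); free-choice trials offer a variable number of
points per target for using reminders against a full reward of 10 points
per target remembered with memory. The normative switch point — the
**optimal indifference point** — solves

```
OIP × ACC_FE = 10 × ACC_FI
```

clamped to the offer range, while the **actual indifference point** (AIP)
is the 50% point of a logistic fitted by maximum likelihood to the binary
strategy choices over offers. The **reminder bias** is `OIP − AIP`
(positive = overuse of reminders). Framing presents the same offers as
gains or as losses; indifference points are estimated on the common
gain-equivalent scale so the framing effect is a pure preference shift.

The package provides:

* **Task engine** — trial schedules of both designs (17-trial
  between-participants sessions with offers 1–9; two 13-trial
  within-participants blocks with offers 2–8), binned target placement,
  Bernoulli trial outcomes.
* **Synthetic participants** — accuracy, metacognitive-confidence and
  choice-policy parameters; lapse-augmented logistic choice with an
  additive loss-framing shift of the indifference point.
* **Measures** — accuracies, OIP, AIP (concave logistic/probit MLE with
  principled boundary handling), reminder bias, metacognitive biases.
* **Screening** — both preregistration-style exclusion pipelines with
  reason codes a–g (accuracy floors, point-biserial choice consistency,
  2.5-SD and 3-scaled-MAD outlier rules).
* **Stats** — 2×2 mixed/within ANOVA with partial η², t tests with d and
  d_z, Pearson correlations, Fisher-z comparison of independent
  correlations, Pearson–Filon / Fisher-z tests for dependent
  non-overlapping correlations, random-intercept mixed-model selection by
  ML AIC/LRT, and paired-t power via the noncentral t distribution.
* **Pipeline** — `run_experiment()` chains everything under a mandatory
  seed; `verify_anchors()` recomputes the arithmetically redundant
  summary statistics of the reference framing studies.

## Worked example

Simulate a within-participants framing experiment with 120 synthetic
participants and run the full analysis battery:

```r
library(remindersim)

report <- run_experiment(run_config(experiment = 2, n_participants = 120,
                                    seed = 42))
report
#> Simulated optimal-reminders experiment 2 (seed 42 )
#>   participants: 120 simulated, 117 after exclusions
#>   analyses: accuracy_anova, bias_t_gain, bias_t_loss, bias_framing_paired, ...

kept <- subset(report$cohort$measures,
               participant_id %in% report$cohort$kept)
aggregate(cbind(acc_fi, acc_fe, oip, aip, reminder_bias) ~ framing,
          kept, function(x) round(mean(x), 2))
#>   framing acc_fi acc_fe oip  aip reminder_bias
#> 1    gain   0.65   0.95 6.7 5.28          1.42
#> 2    loss   0.65   0.94 6.7 5.94          0.76

report$analyses$bias_framing_paired
#> paired t: statistic = 4.1025, df = 116, p = 7.625e-05, d_z = 0.3793
```

Accuracy is ~65% with memory and ~95% with reminders, so the optimal
indifference point sits near 6.7 points. Both framings show a positive
reminder bias (actual switch points below optimal), but the bias is about
0.7 points smaller under loss framing — the framing effect the simulator
builds in through a one-point shift of the subjective indifference point,
here recovered by the paired t test. The model-selection step tells the
same story over and above metacognitive miscalibration:

```r
report$analyses$model_selection$metabias_vs_framing
#>  model k    logLik      AIC
#>     m0 4 -422.6445 853.2890
#>     m1 5 -414.7187 839.4374
#> LRT: chi-square(1) = 15.852, p = 6.851e-05
```

`verify_anchors()` prints a 13-row table of arithmetic consistency checks
on the reference studies' summary statistics (effect sizes from t and n,
AIC-implied likelihood-ratio statistics, the power-analysis n, the
correlation-comparison z), each with its tolerance and pass flag.

A thin command-line front end ships in `inst/exec/remindersim`
(`simulate`, `analyze`, `run`, `verify-anchors`, `power`).

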