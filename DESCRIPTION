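Package: remindersim
Title: Simulation and Analysis of Optimal Reminder Use Under Gain and
    Loss Framing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cognitive offloading with the optimal
    reminders task. Simulates the task's trial structure and synthetic
    participants (internal/external memory accuracy, metacognitive
    confidence, sigmoidal strategy choice with a framing-dependent
    indifference point), estimates optimal and actual indifference
    points and the reminder bias, applies preregistered-style exclusion
    screens (accuracy floors, point-biserial choice consistency, SD and
    MAD outlier rules), and runs the associated inferential battery:
    mixed and repeated-measures 2x2 ANOVA with partial eta squared,
    one-sample and paired t tests with Cohen's d and d_z, Pearson
    correlations, tests for independent and dependent non-overlapping
    correlations, random-intercept mixed-model comparison via AIC and
    likelihood-ratio tests, and paired t-test power via the noncentral
    t distribution.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
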