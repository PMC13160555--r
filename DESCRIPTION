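Package: regimeshift
Title: Regime-Shift Detection Task, System-Neglect Observer Models, and
    Belief-Revision Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how observers detect a shift of a latent
    generative regime from noisy binary signals. Implements the generative
    task (an absorbing two-regime process with per-period transition
    probability and urn-based signal diagnosticity), the normative Bayesian
    change-point observer, the system-neglect family of quasi-Bayesian
    observers with per-level weighting of transition probability and signal
    diagnosticity (including signal-dependent variants), synthetic subject
    populations, per-subject nonlinear least-squares and maximum-likelihood
    fitting with AIC model comparison and parameter-recovery harnesses, the
    Index of Overreaction and behavioral sensitivity slopes, and tests for
    differences between dependent correlations (Meng-style z and subject-wise
    bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
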