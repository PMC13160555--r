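---
title: "Modeling under- and overreaction in regime-shift detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling under- and overreaction in regime-shift detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regimeshift)
```

## The task and the generative model

Each trial of the regime-shift task presents ten sequential signals (red
or blue balls). The trial starts in the red regime; before every period —
including the first — a Bernoulli draw with transition probability $q$
decides whether the latent regime shifts to the blue regime, which is
absorbing: once shifted, all remaining signals come from the blue urn and
at most one shift can occur per trial. Each urn emits its dominant color
with probability $d/(d+1)$, where the diagnosticity $d \ge 1$ is the ratio
of dominant to non-dominant balls; the two urns are symmetric. The design
crosses $q \in \{0.01, 0.05, 0.1\}$ with $d \in \{1.5, 3, 9\}$; every
block presents each of the nine cells once in random order, and the full
per-subject design is 11 blocks (99 trials, 990 periods). Accuracy is
incentivized by a quadratic score, $30\,(0.1 - 0.2\,(P_t - B_t)^2)$ TWD
per estimate, bounded in $[-3, 3]$ and maximized when the reported
probability equals the regime indicator.

`generate_trial()` draws the transition *before* the signal of each
period, so a shift can precede the first signal; this matters for the
first-period posterior, which already mixes prior and likelihood. The
trial length is a parameter (`n_periods`) so that tests can run on short
sequences, but every simulation in this vignette and in the tests uses
the study's ten periods unless stated.

## The Bayesian observer

Writing $r_k = 1$ for a red signal and $0$ for blue, the posterior odds
that the regime has shifted by period $t$ are

$$\frac{P_t}{1-P_t} \;=\;
\frac{1-(1-q)^t}{(1-q)^t}\;
\sum_{j=1}^{t} \frac{q(1-q)^{j-1}}{1-(1-q)^t}\,
d^{\,t+1-j-2\sum_{k=j}^{t} r_k}.$$

The prefactor is the prior odds of a shift by $t$; the sum runs over the
disjoint possible shift times $j$, weighting the likelihood ratio of the
observed history under each by the conditional probability of that shift
time. The exponent counts blue-minus-red signals from $j$ on, so each
post-shift blue signal multiplies the odds by $d$ and each red divides.

Three independent routes to this quantity are implemented —
`bayesian_posterior()` (the closed form above), `posterior_filter()` (a
forward filter on the two-state absorbing chain), and
`posterior_enumerate()` (explicit joint probabilities of the full
history) — and `posterior_oracle()` asserts their agreement to $10^{-10}$.
The closed form is evaluated in log space (`log1p`/`expm1` for the
survival terms, log-sum-exp for the mixture) so large weighting exponents
cannot overflow.

## The system-neglect family

The system-neglect observer responds primarily to signals and only
secondarily to the system parameters. It distorts each parameter with a
per-level weight: the prior odds use the *effective* transition
probability $\alpha q$, and the diagnosticity exponent is multiplied by
$\beta$,

$$\frac{P_t}{1-P_t} \;=\;
\frac{1-(1-\alpha q)^t}{(1-\alpha q)^t}\;
\sum_{j=1}^{t} \frac{q(1-q)^{j-1}}{1-(1-q)^t}\,
d^{\,\beta\,(t+1-j-2\sum_{k=j}^{t} r_k)},$$

with $\alpha = \alpha_i$ dummy-selected by the trial's $q$ level and
$\beta = \beta_j$ by its $d$ level (6 free parameters). All weights equal
to 1 reproduce the Bayesian observer exactly. Lack of sensitivity to the
system parameters appears as $\alpha_1 > \alpha_2 > \alpha_3$ and
$\beta_1 > \beta_2 > \beta_3$: the group means estimated from human data,
$\alpha = (3.69, 1.04, 0.65)$ and $\beta = (1.69, 0.77, 0.57)$, compress
a factor of 10 in objective volatility into a factor of less than 2 in
effective volatility.

Two equation-level choices were genuinely open:

* **Mixture weights.** As written, only the prior odds use $\alpha q$;
  the weights inside the summation keep the raw $q$. We implement exactly
  that, and expose `distort_mixture_weights = TRUE` as a sensitivity
  flag that applies $\alpha q$ inside the weights too (default off
  everywhere, including fitting).
* **Signal dependency.** The signal-dependent variants
  (`sn_sigdep_beta`, `sn_sigdep_alpha`, `sn_sigdep_alphabeta`; 9, 9, 12
  parameters) double the affected family into change-consistent and
  change-inconsistent sets. The set entering the equation at period $t$
  is selected by the *current* period's signal (blue selects the
  consistent set). The alternative — splitting the exponent signal by
  signal across the history — would change the model class rather than
  the parameterization, and does not correspond to estimating parameters
  "at" consistent vs. inconsistent response periods.

Domain constraints: $\alpha \ge 0$ and $\alpha q < 1$ so that
$(1-\alpha q)^t$ remains a survival probability ($\alpha q = 1$ is
accepted as the degenerate certain-shift limit, used only by the
parameter-free observer at $q = 1$); $\beta$ is unconstrained in sign,
and $\beta = 0$ collapses the posterior to the distorted prior
$1-(1-\alpha q)^t$.

## Synthetic subjects

`population_spec()` + `sample_subject_params()` define the cohort model
used everywhere a population is needed. Per-level weights are drawn from
log-normal distributions whose *arithmetic* means equal the group means
above (the log-mean carries the usual $-\sigma^2/2$ correction). The
between-subject distribution of these parameters is an artifact choice,
not an empirical claim: the data motivating the package only report group
means and the correlation structure. The defaults are:

* total log-scale SD 0.35 per family — wide enough that recovery
  correlations are informative, narrow enough that the $\alpha q < 1$
  truncation (draws are redrawn if violated) is essentially never hit;
* a shared subject-level log factor inducing within-family correlation
  0.5 across levels, with the $\alpha$ and $\beta$ families independent —
  mirroring the empirical pattern of positive within-family and null
  cross-family correlations;
* homoscedastic Gaussian response noise added in probability space and
  clipped to $[0,1]$, the heteroscedastic alternative drawing each
  period's SD from the empirically estimated bin vector
  $(0.1015, 0.1296, 0.1987, 0.1929, 0.2061)$ over model-probability bins
  $[0,0.2), \ldots, [0.8,1]$;
* quantization to hundredths (the two-digit button entry) off by default,
  matching the convention of recovery analyses, and available for
  task-realistic simulation.

Clipping was chosen over resampling for boundary handling because it is
simple and transparent; the clipped fraction is recorded as an attribute.
Its side effects are real and the tests treat them explicitly: clipped
noise has smaller realized SD than nominal near the boundaries (the
profiled MLE $\hat\sigma$ estimates the *realized* residual SD), and the
asymmetric truncation near 0 induces residual structure that more
flexible variants can genuinely absorb. Tests that assert pure-Gaussian
properties therefore construct unclipped noise directly.

What the generator does *not* emulate: learning or fatigue across
trials, sequential dependencies beyond the model plus white noise,
rounding strategies, or individual lapses. Passing recovery tests on
this population therefore shows that the fitting machinery is correct
and well-conditioned on the study's design — not that human data meet
the model's assumptions.

## Fitting

`fit_subject()` minimizes the sum of squared deviations between observed
and model probabilities over all non-missing periods, with box
constraints $\alpha_i \in [0, (1-\varepsilon)/q_i]$ and
$\beta_j \in [-10, 10]$ (the wide lower bound keeps the space open;
boundary hits are flagged). The optimizer is Levenberg–Marquardt
(`minpack.lm::nls.lm`) with cost tolerance $10^{-10}$ and a numerical
Jacobian. Multi-start policy: the all-ones start, the group-mean start,
and three random draws; best RSS wins, ties broken by start order.
Fitting operates on the probability estimates themselves (not their log
odds), matching how the model is defined against $P_t$ data.

The `"mle"` method adds a Gaussian noise parameter. Because the Gaussian
likelihood is maximized in its location parameters by the least-squares
solution, the MLE is computed by profiling: $\hat\sigma^2 =
\mathrm{RSS}/n$ (floored at $10^{-4}$), and the AIC is $2(k+1) - 2\log L$
with the noise SD counted. The least-squares path reports the profile
form $n\log(\mathrm{RSS}/n) + 2k + n(1+\log 2\pi)$; the constant is kept
so the two conventions differ by exactly 2 (the extra noise parameter)
on the same data. `compare_models()` summarizes per-subject AICs by
variant and runs paired two-tailed t-tests between variants.

For speed, `prepare_fit_data()` precomputes, per condition, the integer
exponent matrix and mixture-weight matrix of every (trial, period) row;
one objective evaluation is then two vectorized matrix operations per
condition, and a full-design subject fits in well under a second.

## Parameter recovery

`parameter_recovery()` runs the standard four steps — simulate each
subject from its true parameters, refit, correlate truth against
estimates across subjects, repeat while adding noise — at
$\sigma \in \{0.01, 0.05, 0.1, 0.2, 0.3\}$ (a range covering empirical
subject noise) and optionally with the heteroscedastic bin-SD vector.
Truth–estimate pairs are pooled across subjects *and* the three levels
of a family (90 pairs per family for 30 subjects); the level-pooled
convention is reported alongside per-level correlations, since the
source analyses report a single value per family. The default problem
size — 30 subjects, 11 blocks, 10 periods — is the full study design,
and a complete five-level run takes under a minute on one CPU.

The heteroscedastic run is compared against the homoscedastic run at
$\sigma = 0.2$, the level closest to the bin SDs' range (0.10–0.21);
"similar recovery" is operationalized as a pooled-correlation difference
of at most 0.02 per family.

## Bias metrics

**Index of Overreaction.** $IO = \Delta P_t - \Delta P_t^B$ compares the
observer's belief revision with the Bayesian revision; positive means
overreaction. The default window is $t = 2..10$. One numerical fact
discovered in implementation: with equal period weights the window mean
telescopes to $[(P_T - P_1) - (P_T^B - P_1^B)]/(T-1)$, and for the
*noiseless* group-mean observer this leaves the unstable/precise corner
cell statistically indistinguishable from zero. Counting the first
revision against the certain red start ($P_0 = 0$;
`include_first = TRUE`) measures the full belief path and yields the
robust predicted corner signs (overreaction at $q=0.01, d=1.5$,
underreaction at $q=0.1, d=9$); the sign-pattern tests use that option,
while the default follows the $t \ge 2$ convention appropriate for human
data, whose first-period estimates are themselves informative.

**Behavioral slopes.** Sensitivity to a system parameter is the OLS
slope (with intercept, three points) of the subjectively weighted
parameter on its objective level: $\beta_i \ln d_i$ on $\ln d_i$ for
diagnosticity, and the effective transition probability $\alpha_i q_i$
on $q_i$ for volatility. The $q$-family transformation is the direct
analogue of the printed $d$-family construction and reproduces the
boundary slopes exactly — 1 for a Bayesian, 0 for complete neglect
(constant weighted value); alternatives such as weighting log odds were
left out. `neglect_position_tests()` runs one-sample t-tests against 0,
0.5, and 1; `exclude_outlier_slopes()` flags (never drops) slopes outside
$(-0.5, 1.5)$, bounds wide enough to keep essentially all
within-boundary subjects while excluding slopes near 2.

**Regressors.** `design_regressors()` emits the per-period quantities
used in design matrices: $P_t$, $\Delta P_t$, certainty $|P_t - 0.5|$,
period, the signal code $s$ (+1 blue, −1 red), the strength of change
evidence $s\,\ln d$, the intertemporal prior
$\ln\!\big((1-(1-q)^t)/(1-q)^t\big)$, and the action-handedness code of
the two-digit entry (digits 1–5 left hand, 6–9 and 0 right; −1/0/+1 for
left/mixed/right pairs).

## Dependent-correlation tests

`meng_z()` implements the z test for two correlations sharing a
variable: $z = (z_{r_1} - z_{r_2})\sqrt{(N-3)/(2(1-r_x)h)}$ with
$\bar{r}^2 = (r_1^2+r_2^2)/2$, $f = (1-r_x)/(2(1-\bar r^2))$ capped at 1,
and $h = 1 + \bar r^2 (1-f)/(1-\bar r^2)$. Fisher transforms are guarded
at $|r| = 1 - 10^{-12}$. Its two-tailed type-I error at $N=30$ sits
within $[0.03, 0.07]$ over $10^4$ simulated null cohorts.

`bootstrap_corr_diff()` resamples subjects (joint rows) with replacement
— 100,000 resamples by default — and recomputes the correlation
difference per resample. The p-value convention, which the source
analyses leave unstated, is documented rather than asserted: one-tailed,
the add-one-corrected proportion of resamples falling on the opposite
side of zero from the observed difference; degenerate resamples with a
constant column are redrawn and counted.

## Numerical choices and degenerate inputs

* $q = 0$ returns posterior 0 everywhere; $q = 1$ (or $\alpha q = 1$)
  returns 1; $d = 1$ collapses to the prior $1-(1-q)^t$.
* All posterior arithmetic is log-space; exponent magnitudes are bounded
  by $|\beta| \cdot T \cdot \ln d$ and cannot overflow within the bounds.
* Mixture weights normalize to 1 to $10^{-12}$ for all $q \in (0,1]$.
* Missing periods (timed-out responses) are dropped from fitting;
  `n_obs` reflects the drop, and revisions spanning a missing period are
  excluded from IO.
* Fit ties across starts are broken by start order; non-convergence of
  all starts returns a flagged fit object, never a silent result.

## Problem sizes used in the tests

The test suite simulates at the study's native scale where the claim
depends on it (30 subjects × 11 blocks for recovery; $10^5$ trials for
generative frequencies; $10^4$ cohorts for the type-I error) and at
reduced scale (2–6 blocks, 3–5 subjects) for structural checks where
power is not the point. These sizes are the package's own choices and
are stated in the test files.

## Known limitations

* The population model (log-normal, shared-factor correlations) is a
  construction; only its means and correlation signs are anchored to
  reported estimates.
* Boundary clipping makes the Gaussian noise model approximate near 0
  and 1; fits remain consistent in ordering (recovery correlations stay
  above 0.95 at $\sigma = 0.3$) but parameter-level bias appears at high
  noise.
* One latent change per trial, two regimes, known system parameters: no
  learning, drift, or multiple change points.
* The dependent-correlation tools take generic subject vectors; the
  neural vectors they were designed around are external inputs.
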