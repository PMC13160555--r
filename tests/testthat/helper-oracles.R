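# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation: plain scalar
# loops in probability space, no log-space tricks, no precomputation.

# Weighted change-point posterior, written directly from the model
# definition. `alpha`/`beta` may be scalars or length-2 vectors
# (consistent, inconsistent) selected by the current period's signal.
naive_sn_posterior <- function(r, q, d, alpha, beta) {
  T <- length(r)
  P <- numeric(T)
  for (t in seq_len(T)) {
    cls <- if (r[t] == 1) 2L else 1L
    a <- if (length(alpha) == 2) alpha[cls] else alpha
    b <- if (length(beta) == 2) beta[cls] else beta
    aq <- a * q
    if (aq == 0) { P[t] <- 0; next }
    prior_odds <- (1 - (1 - aq)^t) / (1 - aq)^t
    acc <- 0
    for (j in seq_len(t)) {
      expo <- t + 1 - j - 2 * sum(r[j:t])
      w <- q * (1 - q)^(j - 1) / (1 - (1 - q)^t)
      acc <- acc + w * d^(b * expo)
    }
    odds <- prior_odds * acc
    P[t] <- odds / (1 + odds)
  }
  P
}

# Textbook one-sample t statistic.
naive_t_stat <- function(x, mu) {
  (mean(x) - mu) / (sd(x) / sqrt(length(x)))
}

# Independent evaluation of the dependent-correlation z formula.
naive_meng_z <- function(r1, r2, rx, N) {
  zr1 <- 0.5 * log((1 + r1) / (1 - r1))
  zr2 <- 0.5 * log((1 + r2) / (1 - r2))
  rb2 <- (r1 * r1 + r2 * r2) / 2
  f <- (1 - rx) / (2 * (1 - rb2))
  if (f > 1) f <- 1
  h <- (1 - f * rb2) / (1 - rb2)
  (zr1 - zr2) * sqrt((N - 3) / (2 * (1 - rx) * h))
}

# Closed-form simple OLS slope through three points.
naive_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Small simulated cohort in the flat deposited-table format (synthetic
# stand-in for the archived human data; same columns, model-generated).
make_synthetic_flat_cohort <- function(n_subjects = 4, n_blocks = 3,
                                       sigma = 0.1, seed = 99) {
  set.seed(seed)
  spec <- population_spec(noise = sigma)
  truth <- sample_subject_params(spec, n_subjects)
  trials <- simulate_task(n_subjects, n_blocks)
  est <- simulate_estimates(trials, truth)
  list(
    flat = est[c("subject_id", "block", "trial", "q", "d", "period",
                 "signal", "P")],
    truth = truth
  )
}
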