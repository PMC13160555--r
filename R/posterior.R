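#' @keywords internal
#' Encode signals as the red indicator r (1 = red, 0 = blue)
signal_code <- function(signals) {
  if (is.numeric(signals)) {
    if (!all(signals %in% c(0, 1))) {
      stop("numeric signals must be 0 (blue) or 1 (red)", call. = FALSE)
    }
    return(as.integer(signals))
  }
  if (!all(signals %in% c("red", "blue"))) {
    stop("signals must be \"red\"/\"blue\" or 0/1", call. = FALSE)
  }
  as.integer(signals == "red")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Posterior probability of a regime shift under per-period weighting
#'
#' Core change-point posterior. At period t the posterior odds of the regime
#' having shifted are the prior odds of a shift by t times a mixture, over
#' all disjoint shift times j = 1..t, of the diagnosticity likelihood ratio
#' raised to the (possibly weighted) signal-count exponent:
#'
#' odds_t = (1-(1-aq)^t)/(1-aq)^t *
#'          sum_j q(1-q)^(j-1)/(1-(1-q)^t) * d^(b*(t+1-j-2*sum_{k=j}^t r_k))
#'
#' with r_k = 1 for a red signal and 0 for blue. With a = b = 1 this is the
#' exact Bayesian posterior; general (a, b) give the system-neglect observer,
#' where only the prior odds use the distorted transition probability a*q and
#' the mixture weights keep the raw q. Computation is in log space, so large
#' weighting exponents do not overflow.
#'
#' @param r integer vector of red indicators for periods 1..T.
#' @param q transition probability.
#' @param d signal diagnosticity (>= 1).
#' @param alpha_t per-period transition-probability weight (recycled).
#' @param beta_t per-period diagnosticity weight (recycled).
#' @param distort_mixture_weights if TRUE the mixture weights inside the
#'   summation also use the distorted a*q (sensitivity analysis; default
#'   FALSE, the printed model).
#' @return numeric vector of posterior probabilities P_t, t = 1..T.
#' @keywords internal
posterior_core <- function(r, q, d, alpha_t = 1, beta_t = 1,
                           distort_mixture_weights = FALSE) {
  T <- length(r)
  alpha_t <- rep_len(alpha_t, T)
  beta_t <- rep_len(beta_t, T)
  if (any(alpha_t < 0)) stop("alpha must be >= 0", call. = FALSE)
  if (any(alpha_t * q > 1)) {
    stop("alpha * q must be < 1 for a valid survival probability",
         call. = FALSE)
  }
  cs <- c(0, cumsum(r))
  logd <- log(d)
  P <- numeric(T)
  for (t in seq_len(T)) {
    aq <- alpha_t[t] * q
    if (aq == 0) { P[t] <- 0; next }
    if (aq == 1) { P[t] <- 1; next }  # certain immediate transition
    # log prior odds of a shift by t
    log_surv <- t * log1p(-aq)
    log_prior_odds <- log(-expm1(log_surv)) - log_surv
    wq <- if (distort_mixture_weights) aq else q
    j <- seq_len(t)
    e <- (t + 1 - j) - 2 * (cs[t + 1] - cs[j])
    if (wq == 1) {
      logw <- ifelse(j == 1, 0, -Inf)
    } else {
      logw <- log(wq) + (j - 1) * log1p(-wq) - log(-expm1(t * log1p(-wq)))
    }
    lo <- log_prior_odds + logsumexp(logw + beta_t[t] * e * logd)
    P[t] <- stats::plogis(lo)
  }
  P
}

#' Bayesian change-point posterior
#'
#' Normative posterior probability that the regime has shifted to blue by
#' each period, given the signal history, the per-period transition
#' probability `q`, and the signal diagnosticity `d`. The blue regime is
#' absorbing, so the posterior mixes over all disjoint shift times.
#'
#' @param signals character vector ("red"/"blue") or 0/1 red indicators.
#' @inheritParams posterior_core
#' @return numeric vector of Bayesian posteriors, one per period.
#' @examples
#' bayesian_posterior("blue", q = 0.1, d = 9)  # 0.5
#' bayesian_posterior("red", q = 0.1, d = 9)   # 1/82
#' @export
bayesian_posterior <- function(signals, q, d) {
  check_q(q)
  check_d(d)
  posterior_core(signal_code(signals), q, d, 1, 1)
}

#' Recursive two-state filter for the change-point posterior
#'
#' Independent route to the Bayesian posterior: a forward filter over the
#' two-regime hidden Markov chain with absorbing blue state. Before each
#' signal the belief is propagated through the transition
#' (prior = post + (1 - post) * q) and then updated by the single-period
#' likelihood ratio (d for blue, 1/d for red).
#'
#' @inheritParams bayesian_posterior
#' @return numeric vector of posteriors, one per period.
#' @export
posterior_filter <- function(signals, q, d) {
  check_q(q)
  check_d(d)
  r <- signal_code(signals)
  post <- 0
  P <- numeric(length(r))
  for (t in seq_along(r)) {
    prior <- post + (1 - post) * q
    if (prior == 0) { P[t] <- 0; post <- 0; next }
    if (prior == 1) { P[t] <- 1; post <- 1; next }
    lr <- if (r[t] == 1L) 1 / d else d
    odds <- prior / (1 - prior) * lr
    post <- odds / (1 + odds)
    P[t] <- post
  }
  P
}

#' Enumeration route to the change-point posterior
#'
#' Second independent route: explicit enumeration of the disjoint shift
#' times, computing the exact joint probability of the full signal history
#' under each (no shift; shift at j = 1..t) and normalizing.
#'
#' @inheritParams bayesian_posterior
#' @return numeric vector of posteriors, one per period.
#' @export
posterior_enumerate <- function(signals, q, d) {
  check_q(q)
  check_d(d)
  r <- signal_code(signals)
  p_red_urn <- ifelse(r == 1L, d / (d + 1), 1 / (d + 1))
  p_blue_urn <- ifelse(r == 1L, 1 / (d + 1), d / (d + 1))
  T <- length(r)
  P <- numeric(T)
  for (t in seq_len(T)) {
    p_no <- (1 - q)^t * prod(p_red_urn[seq_len(t)])
    p_shift <- 0
    for (j in seq_len(t)) {
      before <- if (j > 1) prod(p_red_urn[seq_len(j - 1)]) else 1
      after <- prod(p_blue_urn[j:t])
      p_shift <- p_shift + q * (1 - q)^(j - 1) * before * after
    }
    tot <- p_no + p_shift
    P[t] <- if (tot == 0) 0 else p_shift / tot
  }
  P
}

#' Cross-checked Bayesian posterior
#'
#' Computes the posterior by the closed form ([bayesian_posterior()]), the
#' recursive filter ([posterior_filter()]), and explicit enumeration
#' ([posterior_enumerate()]), asserts that all three agree to `tol`, and
#' returns the closed-form series. Intended for verification; the three
#' routes share no code.
#'
#' @inheritParams bayesian_posterior
#' @param tol maximum tolerated absolute disagreement between routes.
#' @return numeric vector of posteriors, one per period.
#' @export
posterior_oracle <- function(signals, q, d, tol = 1e-10) {
  a <- bayesian_posterior(signals, q, d)
  b <- posterior_filter(signals, q, d)
  c_ <- posterior_enumerate(signals, q, d)
  if (max(abs(a - b), abs(a - c_), abs(b - c_)) > tol) {
    stop("posterior routes disagree beyond tolerance ", tol, call. = FALSE)
  }
  a
}

#' Intertemporal prior log odds of a shift
#'
#' `ln((1-(1-q)^t) / (1-q)^t)`: the log odds that the regime has shifted by
#' period t given the transition probability alone. Strictly increasing in t.
#'
#' @param q transition probability in (0, 1).
#' @param t period index (>= 1), vectorized.
#' @return numeric vector of log odds.
#' @examples
#' prior_log_odds(0.5, 1)  # 0
#' prior_log_odds(0.1, 1)  # log(1/9)
#' @export
prior_log_odds <- function(q, t) {
  if (any(q <= 0) || any(q >= 1)) {
    stop("`q` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(all(t >= 1))
  log_surv <- t * log1p(-q)
  log(-expm1(log_surv)) - log_surv
}
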