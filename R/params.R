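#' Model variants
#'
#' Names of the observer-model variants: the parameter-free Bayesian
#' observer, the original system-neglect model (one weight per level of each
#' system parameter, 6 parameters), and the signal-dependent variants in
#' which the diagnosticity weights, the transition-probability weights, or
#' both are estimated separately at change-consistent (blue) and
#' change-inconsistent (red) signals (9, 9, and 12 parameters).
#'
#' @return character vector of variant names.
#' @export
sn_variants <- function() {
  c("bayes", "sn_original", "sn_sigdep_beta", "sn_sigdep_alpha",
    "sn_sigdep_alphabeta")
}

sigdep_classes <- c("consistent", "inconsistent")

as_class_matrix <- function(x, what) {
  if (is.matrix(x)) {
    if (!identical(dim(x), c(2L, 3L))) {
      stop(what, " must be a length-3 vector or a 2x3 matrix", call. = FALSE)
    }
    rownames(x) <- sigdep_classes
    return(x)
  }
  if (length(x) != 3L) {
    stop(what, " must have one value per level (length 3)", call. = FALSE)
  }
  matrix(rep(as.numeric(x), each = 2), 2, 3, dimnames = list(sigdep_classes))
}

#' Subject-level weighting parameters
#'
#' Container for the per-level weights of the system-neglect family. `alpha`
#' weights the transition probability (the observer's effective transition
#' probability at level i is `alpha[i] * q[i]`); `beta` weights the signal
#' diagnosticity (the odds update per signal uses `d[j]^beta[j]`). Under the
#' signal-dependent variants the affected family carries separate
#' "consistent" (blue signal) and "inconsistent" (red signal) rows.
#'
#' @param alpha numeric length-3 vector, or 2x3 matrix with rows
#'   `consistent`/`inconsistent` for the signal-dependent alpha variants.
#' @param beta numeric length-3 vector or 2x3 matrix, as `alpha`.
#' @param variant one of [sn_variants()].
#' @param sigma optional response-noise standard deviation.
#' @param q,d the system-parameter levels the weights are keyed to.
#' @return object of class `sn_params`.
#' @examples
#' sn_params(alpha = c(3.69, 1.04, 0.65), beta = c(1.69, 0.77, 0.57))
#' @export
sn_params <- function(alpha = rep(1, 3), beta = rep(1, 3),
                      variant = "sn_original", sigma = NULL,
                      q = q_levels(), d = d_levels()) {
  variant <- match.arg(variant, sn_variants())
  if (variant == "bayes") {
    alpha <- rep(1, 3)
    beta <- rep(1, 3)
  }
  alpha_dep <- variant %in% c("sn_sigdep_alpha", "sn_sigdep_alphabeta")
  beta_dep <- variant %in% c("sn_sigdep_beta", "sn_sigdep_alphabeta")
  if (alpha_dep && !is.matrix(alpha)) {
    stop("variant ", variant, " needs a 2x3 `alpha` (consistent/inconsistent)",
         call. = FALSE)
  }
  if (beta_dep && !is.matrix(beta)) {
    stop("variant ", variant, " needs a 2x3 `beta` (consistent/inconsistent)",
         call. = FALSE)
  }
  if (!alpha_dep && is.matrix(alpha)) {
    stop("variant ", variant, " takes a length-3 `alpha`", call. = FALSE)
  }
  if (!beta_dep && is.matrix(beta)) {
    stop("variant ", variant, " takes a length-3 `beta`", call. = FALSE)
  }
  A <- as_class_matrix(alpha, "`alpha`")
  B <- as_class_matrix(beta, "`beta`")
  if (any(!is.finite(A)) || any(!is.finite(B))) {
    stop("parameters must be finite", call. = FALSE)
  }
  if (any(A < 0)) stop("alpha must be >= 0", call. = FALSE)
  if (any(sweep(A, 2, q, `*`) >= 1)) {
    stop("alpha * q must be < 1 at every level", call. = FALSE)
  }
  structure(
    list(alpha = A, beta = B, variant = variant, sigma = sigma,
         q = q, d = d),
    class = "sn_params"
  )
}

#' @export
print.sn_params <- function(x, ...) {
  cat("<sn_params> variant:", x$variant, "\n")
  cat("alpha (q levels ", paste(x$q, collapse = ", "), "):\n", sep = "")
  print(round(x$alpha, 4))
  cat("beta (d levels ", paste(x$d, collapse = ", "), "):\n", sep = "")
  print(round(x$beta, 4))
  if (!is.null(x$sigma)) cat("sigma:", x$sigma, "\n")
  invisible(x)
}

#' Number of free parameters of a variant
#'
#' @param variant one of [sn_variants()].
#' @return integer count (0 for the Bayesian observer).
#' @export
n_free_params <- function(variant) {
  variant <- match.arg(variant, sn_variants())
  switch(variant,
    bayes = 0L, sn_original = 6L, sn_sigdep_beta = 9L,
    sn_sigdep_alpha = 9L, sn_sigdep_alphabeta = 12L
  )
}

#' Posterior series for one trial under an `sn_params` observer
#'
#' Selects the per-level weights via the trial's condition and, for
#' signal-dependent variants, the current period's signal class (blue =
#' consistent with change, red = inconsistent), then evaluates the
#' system-neglect posterior.
#'
#' @param signals signal vector for the trial ("red"/"blue" or 0/1).
#' @param q_level,d_level 1-based level indices of the trial's condition.
#' @param params an [sn_params()] object.
#' @param distort_mixture_weights see [posterior_core()].
#' @return numeric vector of posteriors P_t.
#' @export
sn_posterior_trial <- function(signals, q_level, d_level, params,
                               distort_mixture_weights = FALSE) {
  stopifnot(inherits(params, "sn_params"))
  r <- signal_code(signals)
  cls <- ifelse(r == 1L, 2L, 1L)  # row 1 consistent (blue), row 2 inconsistent
  alpha_t <- params$alpha[cls, q_level]
  beta_t <- params$beta[cls, d_level]
  posterior_core(r, params$q[q_level], params$d[d_level], alpha_t, beta_t,
                 distort_mixture_weights)
}

#' System-neglect posterior for one condition
#'
#' Convenience wrapper evaluating the weighted posterior with scalar
#' weights `alpha` and `beta` for a single (q, d) condition. `alpha = beta
#' = 1` reproduces [bayesian_posterior()]; `beta = 0` ignores the signals and
#' returns the distorted prior probability `1 - (1 - alpha*q)^t`.
#'
#' @inheritParams bayesian_posterior
#' @param alpha transition-probability weight (alpha * q must be < 1).
#' @param beta diagnosticity weight.
#' @param distort_mixture_weights see [posterior_core()].
#' @return numeric vector of posteriors P_t.
#' @examples
#' system_neglect_posterior("blue", q = 0.01, d = 1.5,
#'                          alpha = 3.69, beta = 1.69)  # ~0.0707
#' @export
system_neglect_posterior <- function(signals, q, d, alpha = 1, beta = 1,
                                     distort_mixture_weights = FALSE) {
  check_q(q)
  check_d(d)
  posterior_core(signal_code(signals), q, d, alpha, beta,
                 distort_mixture_weights)
}

#' Model posterior for every period of a long trial table
#'
#' Applies an `sn_params` observer to each trial of a long-format table (as
#' from [simulate_task()]) and returns the posterior aligned with its rows.
#'
#' @param trials long-format data.frame with columns `subject_id`, `block`,
#'   `trial`, `q_level`, `d_level`, `period`, `signal`.
#' @param params an [sn_params()] object (use
#'   `sn_params(variant = "bayes")` for the Bayesian observer).
#' @param distort_mixture_weights see [posterior_core()].
#' @return numeric vector, one posterior per row of `trials`.
#' @export
model_posterior <- function(trials, params,
                            distort_mixture_weights = FALSE) {
  stopifnot(inherits(params, "sn_params"))
  key <- interaction(trials$subject_id, trials$block, trials$trial,
                     drop = TRUE)
  P <- numeric(nrow(trials))
  for (idx in split(seq_len(nrow(trials)), key)) {
    idx <- idx[order(trials$period[idx])]
    P[idx] <- sn_posterior_trial(
      trials$signal[idx], trials$q_level[idx][1], trials$d_level[idx][1],
      params, distort_mixture_weights
    )
  }
  P
}
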