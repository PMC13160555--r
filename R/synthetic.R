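#' Population specification for synthetic subjects
#'
#' Describes the between-subject distribution of the weighting parameters
#' and the response-noise model. Parameters are drawn from log-normal
#' distributions whose arithmetic means equal `alpha_mean` / `beta_mean`
#' (the defaults are the group means estimated from human data: alpha =
#' 3.69, 1.04, 0.65 over the three transition-probability levels and beta =
#' 1.69, 0.77, 0.57 over the three diagnosticity levels). Within each family
#' the three levels share a subject-level log-scale factor, which induces
#' positive within-family correlation while the alpha and beta families stay
#' independent — the structure observed in the human cohort.
#'
#' @param alpha_mean,beta_mean per-level population means.
#' @param log_sd total between-subject SD on the log scale (per family).
#' @param within_cor within-family correlation of log parameters induced by
#'   the shared factor (0 <= within_cor <= 1).
#' @param noise either a single homoscedastic response-noise SD, or a
#'   length-5 vector of bin SDs over model-probability bins \[0,0.2), ...,
#'   \[0.8,1\] for heteroscedastic noise. The default heteroscedastic vector
#'   used by [parameter_recovery()] is the empirically estimated
#'   `c(0.1015, 0.1296, 0.1987, 0.1929, 0.2061)`.
#' @param quantize should estimates be rounded to hundredths (two-digit
#'   button entry)? Default FALSE, the convention for recovery studies.
#' @param q,d system-parameter levels.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(alpha_mean = c(3.69, 1.04, 0.65),
                            beta_mean = c(1.69, 0.77, 0.57),
                            log_sd = 0.35, within_cor = 0.5,
                            noise = 0.1, quantize = FALSE,
                            q = q_levels(), d = d_levels()) {
  stopifnot(length(alpha_mean) == 3, length(beta_mean) == 3,
            log_sd >= 0, within_cor >= 0, within_cor <= 1,
            length(noise) %in% c(1L, 5L), all(noise >= 0))
  structure(
    list(alpha_mean = alpha_mean, beta_mean = beta_mean, log_sd = log_sd,
         within_cor = within_cor, noise = noise, quantize = quantize,
         q = q, d = d),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat("alpha means:", paste(x$alpha_mean, collapse = ", "), "\n")
  cat("beta means: ", paste(x$beta_mean, collapse = ", "), "\n")
  cat("log-scale SD:", x$log_sd, " within-family cor:", x$within_cor, "\n")
  cat("noise:", if (length(x$noise) == 1) paste0("homoscedastic sd = ", x$noise)
      else paste0("heteroscedastic bin SDs = ",
                  paste(x$noise, collapse = ", ")), "\n")
  cat("quantize:", x$quantize, "\n")
  invisible(x)
}

draw_family <- function(means, log_sd, within_cor, n) {
  # shared subject factor + idiosyncratic level noise on the log scale;
  # log-mean shifted by -log_sd^2/2 so arithmetic means equal `means`
  sd_shared <- log_sd * sqrt(within_cor)
  sd_idio <- log_sd * sqrt(1 - within_cor)
  shared <- stats::rnorm(n, 0, sd_shared)
  z <- shared + matrix(stats::rnorm(n * 3, 0, sd_idio), n, 3)
  sweep(exp(z), 2, means * exp(-log_sd^2 / 2), `*`)
}

#' Draw subject parameters from a population
#'
#' Samples `n` subjects' alpha and beta vectors from the log-normal
#' population of a [population_spec()]. Draws violating the constraint
#' `alpha * q < 1` at any level are redrawn (the log-normal tail beyond that
#' bound is negligible at the default dispersion).
#'
#' @param spec a [population_spec()].
#' @param n number of subjects.
#' @return list of [sn_params()] objects (variant `sn_original`), with the
#'   spec's noise model attached as `sigma` when homoscedastic.
#' @examples
#' set.seed(1)
#' sample_subject_params(population_spec(), 2)[[1]]
#' @export
sample_subject_params <- function(spec, n) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  A <- draw_family(spec$alpha_mean, spec$log_sd, spec$within_cor, n)
  B <- draw_family(spec$beta_mean, spec$log_sd, spec$within_cor, n)
  bound <- (1 - 1e-9) / spec$q
  for (i in seq_len(n)) {
    tries <- 0
    while (any(A[i, ] * spec$q >= 1)) {
      A[i, ] <- draw_family(spec$alpha_mean, spec$log_sd, spec$within_cor, 1)
      tries <- tries + 1
      if (tries > 1000) stop("population spec infeasible: alpha*q < 1 ",
                             "cannot be satisfied", call. = FALSE)
    }
    A[i, ] <- pmin(A[i, ], bound)
  }
  sigma <- if (length(spec$noise) == 1) spec$noise else NULL
  lapply(seq_len(n), function(i) {
    sn_params(alpha = A[i, ], beta = B[i, ], variant = "sn_original",
              sigma = sigma, q = spec$q, d = spec$d)
  })
}

bin_index <- function(p) {
  # five probability bins [0,.2), [.2,.4), [.4,.6), [.6,.8), [.8,1]
  pmin(pmax(floor(p * 5) + 1L, 1L), 5L)
}

#' Simulate probability estimates for a trial table
#'
#' Computes the observer's noiseless posterior for every period, adds
#' independent Gaussian response noise, clips to \[0, 1\], and optionally
#' quantizes to hundredths. With heteroscedastic noise the per-period SD is
#' selected from the 5-bin vector by the *noiseless model* probability.
#'
#' @param trials long trial table (see [simulate_task()]).
#' @param params an [sn_params()] object, or a list of one per subject in
#'   `sort(unique(trials$subject_id))` order.
#' @param noise homoscedastic SD (scalar) or length-5 bin-SD vector; if
#'   `NULL`, taken from `params$sigma` (0 when that is also NULL).
#' @param quantize round estimates to two digits?
#' @return `trials` with columns `P_model` (noiseless posterior), `P`
#'   (noisy estimate) and `missing` (all FALSE) appended. The fraction of
#'   periods moved by clipping is attached as attribute `clipped_fraction`.
#' @export
simulate_estimates <- function(trials, params, noise = NULL,
                               quantize = FALSE) {
  subjects <- sort(unique(trials$subject_id))
  if (inherits(params, "sn_params")) {
    params <- rep(list(params), length(subjects))
  }
  stopifnot(length(params) == length(subjects))
  P_model <- numeric(nrow(trials))
  for (i in seq_along(subjects)) {
    idx <- trials$subject_id == subjects[i]
    P_model[idx] <- model_posterior(trials[idx, , drop = FALSE], params[[i]])
  }
  if (is.null(noise)) {
    noise <- params[[1]]$sigma
    if (is.null(noise)) noise <- 0
  }
  stopifnot(length(noise) %in% c(1L, 5L), all(noise >= 0))
  sds <- if (length(noise) == 1) rep(noise, nrow(trials))
         else noise[bin_index(P_model)]
  raw <- P_model + stats::rnorm(nrow(trials), 0, sds)
  P <- pmin(pmax(raw, 0), 1)
  clipped <- mean(raw != P)
  if (quantize) P <- round(P, 2)
  out <- trials
  out$P_model <- P_model
  out$P <- P
  out$missing <- FALSE
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Mark periods missing at random
#'
#' Emulates timed-out responses: flags each period missing independently
#' with probability `p_missing`. Downstream fitting drops flagged periods.
#'
#' @param estimates table from [simulate_estimates()].
#' @param p_missing probability in \[0, 1) of a period being missing.
#' @return `estimates` with its `missing` column updated (`P` set to `NA`
#'   on missing periods).
#' @export
simulate_missing <- function(estimates, p_missing) {
  stopifnot(p_missing >= 0, p_missing < 1)
  if (p_missing == 0) return(estimates)
  miss <- stats::runif(nrow(estimates)) < p_missing
  estimates$missing <- estimates$missing | miss
  estimates$P[estimates$missing] <- NA_real_
  estimates
}
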