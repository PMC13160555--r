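#' Parameter-recovery harness
#'
#' Runs the four-step recovery procedure: draw each synthetic subject's true
#' weighting parameters from the population, simulate the subject's
#' probability estimates on a fresh randomized design under the
#' system-neglect model, add Gaussian response noise, refit, and correlate
#' true against recovered values across subjects. Truth-estimate pairs are
#' pooled across subjects and the three levels of a family (alpha or beta),
#' and per-level correlations are reported as well. Noise levels may be
#' homoscedastic SDs or length-5 bin-SD vectors (heteroscedastic, indexed by
#' the noiseless model probability).
#'
#' @param spec a [population_spec()].
#' @param noise_levels numeric vector of homoscedastic SDs, or a list whose
#'   elements are scalars and/or length-5 bin-SD vectors. Default: the five
#'   homoscedastic study levels 0.01, 0.05, 0.1, 0.2, 0.3.
#' @param n_subjects cohort size (default 30).
#' @param n_blocks blocks per subject (default 11: the full design, 99
#'   trials, 990 periods).
#' @param n_periods periods per trial.
#' @param seed optional integer seed.
#' @param n_random_starts multi-starts passed to [fit_subject()].
#' @return object of class `sn_recovery`: `results` (one row per noise
#'   level, family, and level — `"pooled"` plus `"1"`..`"3"` — with Pearson
#'   `r` and the pair count), `pairs` (the truth/estimate scatter data),
#'   `n_subjects`, `n_blocks`, `seed`, and the fraction of fits that
#'   converged.
#' @examples
#' \donttest{
#' rec <- parameter_recovery(population_spec(), noise_levels = 0.1,
#'                           n_subjects = 4, n_blocks = 2, seed = 1)
#' subset(rec$results, level == "pooled")
#' }
#' @export
parameter_recovery <- function(spec = population_spec(),
                               noise_levels = c(0.01, 0.05, 0.1, 0.2, 0.3),
                               n_subjects = 30L, n_blocks = 11L,
                               n_periods = 10L, seed = NULL,
                               n_random_starts = 3L) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(noise_levels)) noise_levels <- as.list(noise_levels)
  labels <- vapply(noise_levels, function(x) {
    if (length(x) == 1) format(x) else "heteroscedastic"
  }, "")
  truth <- sample_subject_params(spec, n_subjects)
  trials <- simulate_task(n_subjects, n_blocks, n_periods,
                          condition_grid(spec$q, spec$d))
  base <- simulate_estimates(trials, truth, noise = 0)
  true_tab <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject_id = s, family = rep(c("alpha", "beta"), each = 3),
               level = rep(1:3, 2),
               true = c(truth[[s]]$alpha[1, ], truth[[s]]$beta[1, ]))
  }))
  results <- list(); pairs_all <- list(); n_conv <- 0L; n_fit <- 0L
  for (li in seq_along(noise_levels)) {
    noise <- noise_levels[[li]]
    est <- base
    sds <- if (length(noise) == 1) rep(noise, nrow(base))
           else noise[bin_index(base$P_model)]
    est$P <- pmin(pmax(base$P_model + stats::rnorm(nrow(base), 0, sds), 0), 1)
    if (spec$quantize) est$P <- round(est$P, 2)
    fit_rows <- list()
    for (s in seq_len(n_subjects)) {
      f <- fit_subject(est[est$subject_id == s, , drop = FALSE],
                       variant = "sn_original",
                       n_random_starts = n_random_starts,
                       q = spec$q, d = spec$d)
      n_fit <- n_fit + 1L
      if (!isTRUE(f$converged)) {
        warning("fit for subject ", s, " at noise level ", labels[li],
                " did not converge; excluded", call. = FALSE)
        next
      }
      n_conv <- n_conv + 1L
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        subject_id = s, family = rep(c("alpha", "beta"), each = 3),
        level = rep(1:3, 2),
        est = c(f$params$alpha[1, ], f$params$beta[1, ])
      )
    }
    fit_tab <- do.call(rbind, fit_rows)
    pairs <- merge(true_tab, fit_tab,
                   by = c("subject_id", "family", "level"))
    pairs$noise <- labels[li]
    pairs_all[[li]] <- pairs
    for (fam in c("alpha", "beta")) {
      sub <- pairs[pairs$family == fam, ]
      res <- data.frame(
        noise = labels[li], family = fam,
        level = c("pooled", "1", "2", "3"),
        r = c(stats::cor(sub$true, sub$est),
              vapply(1:3, function(l) {
                sl <- sub[sub$level == l, ]
                stats::cor(sl$true, sl$est)
              }, 0)),
        n_pairs = c(nrow(sub), vapply(1:3, function(l) {
          sum(sub$level == l)
        }, 0L))
      )
      results[[length(results) + 1L]] <- res
    }
  }
  structure(
    list(results = do.call(rbind, results),
         pairs = do.call(rbind, pairs_all),
         n_subjects = n_subjects, n_blocks = n_blocks,
         n_periods = n_periods, seed = seed,
         convergence_rate = n_conv / n_fit),
    class = "sn_recovery"
  )
}

#' @export
print.sn_recovery <- function(x, ...) {
  cat("<sn_recovery> ", x$n_subjects, " subjects x ", x$n_blocks,
      " blocks; convergence ", round(100 * x$convergence_rate, 1), "%\n",
      sep = "")
  print(x$results[x$results$level == "pooled", ], row.names = FALSE)
  invisible(x)
}

#' Minimum pooled recovery correlation per family
#'
#' @param rec an `sn_recovery` object.
#' @return named numeric vector with elements `alpha` and `beta`: the
#'   minimum over noise levels of the pooled truth-estimate Pearson r.
#' @export
recovery_min_r <- function(rec) {
  stopifnot(inherits(rec, "sn_recovery"))
  pooled <- rec$results[rec$results$level == "pooled", ]
  c(alpha = min(pooled$r[pooled$family == "alpha"]),
    beta = min(pooled$r[pooled$family == "beta"]))
}

#' Residual standard deviation by probability bin
#'
#' Splits periods into five probability bins (\[0,0.2), \[0.2,0.4),
#' \[0.4,0.6), \[0.6,0.8), \[0.8,1\]) and returns the SD of the residual
#' `P_obs - P_model` within each bin. The bin is indexed by the model
#' probability by default (set `by = "observed"` to index by the observed
#' estimate instead). Empty bins yield `NA`, not zero.
#'
#' @param P_obs observed probability estimates.
#' @param P_model model (fitted) probabilities, same length.
#' @param by `"model"` or `"observed"` bin indexing.
#' @return data.frame with columns `bin`, `lower`, `upper`, `sd`, `n`.
#' @export
residual_sd_by_bin <- function(P_obs, P_model, by = c("model", "observed")) {
  by <- match.arg(by)
  stopifnot(length(P_obs) == length(P_model))
  ok <- !is.na(P_obs) & !is.na(P_model)
  P_obs <- P_obs[ok]; P_model <- P_model[ok]
  bins <- bin_index(if (by == "model") P_model else P_obs)
  resid <- P_obs - P_model
  data.frame(
    bin = 1:5, lower = seq(0, 0.8, 0.2), upper = seq(0.2, 1, 0.2),
    sd = vapply(1:5, function(b) {
      if (sum(bins == b) >= 2) stats::sd(resid[bins == b]) else NA_real_
    }, 0),
    n = vapply(1:5, function(b) sum(bins == b), 0L)
  )
}
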