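sim_subject <- function(params, n_blocks = 4, sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- simulate_task(1, n_blocks = n_blocks)
  simulate_estimates(tr, params, noise = sigma)
}

random_params <- function(variant) {
  draw_vec <- function() c(exp(runif(1, log(0.5), log(8))),
                           exp(runif(1, log(0.4), log(2.5))),
                           exp(runif(1, log(0.3), log(2))))
  draw_beta <- function() runif(3, 0.3, 2.2)
  dep_a <- variant %in% c("sn_sigdep_alpha", "sn_sigdep_alphabeta")
  dep_b <- variant %in% c("sn_sigdep_beta", "sn_sigdep_alphabeta")
  a <- if (dep_a) rbind(draw_vec(), draw_vec()) else draw_vec()
  b <- if (dep_b) rbind(draw_beta(), draw_beta()) else draw_beta()
  sn_params(alpha = a, beta = b, variant = variant)
}

test_that("noiseless fits recover the generating parameters", {
  set.seed(41)
  for (i in 1:20) {
    p <- random_params("sn_original")
    est <- sim_subject(p, n_blocks = 4)
    f <- fit_subject(est)
    expect_true(f$converged)
    truth <- c(p$alpha[1, ], p$beta[1, ])
    expect_lt(max(abs(f$theta - truth)), 1e-4)
  }
})

test_that("noiseless fits recover signal-dependent variants as well", {
  set.seed(42)
  for (variant in c("sn_sigdep_beta", "sn_sigdep_alpha",
                    "sn_sigdep_alphabeta")) {
    for (i in 1:3) {
      p <- random_params(variant)
      est <- sim_subject(p, n_blocks = 6)
      f <- fit_subject(est, variant = variant)
      expect_true(f$converged)
      expect_lt(max(abs(f$params$alpha - p$alpha)), 2e-3)
      expect_lt(max(abs(f$params$beta - p$beta)), 2e-3)
    }
  }
})

test_that("data from a Bayesian responder yield weights near one", {
  set.seed(43)
  est <- sim_subject(sn_params(variant = "bayes"), n_blocks = 11,
                     sigma = 0.05)
  f <- fit_subject(est)
  expect_true(all(abs(f$theta - 1) < 0.25))
})

test_that("profiled MLE recovers the noise SD on unclipped data", {
  set.seed(44)
  p <- sn_params(alpha = c(3.69, 1.04, 0.65), beta = c(1.69, 0.77, 0.57))
  est <- sim_subject(p, n_blocks = 11, sigma = 0)
  # add unclipped noise directly so the Gaussian assumption holds exactly
  est$P <- est$P_model + rnorm(nrow(est), 0, 0.15)
  f <- fit_subject(est, method = "mle")
  expect_gt(f$sigma_hat, 0.14)
  expect_lt(f$sigma_hat, 0.16)
  # on clipped data sigma_hat tracks the realized residual spread instead
  est2 <- sim_subject(p, n_blocks = 11, sigma = 0.15)
  f2 <- fit_subject(est2, method = "mle")
  expect_lt(abs(f2$sigma_hat - sd(est2$P - est2$P_model)), 0.02)
})

test_that("least-squares and MLE point estimates coincide", {
  set.seed(45)
  p <- random_params("sn_original")
  est <- sim_subject(p, n_blocks = 6, sigma = 0.1)
  f1 <- fit_subject(est, method = "nls")
  f2 <- fit_subject(est, method = "mle")
  expect_lt(max(abs(f1$theta - f2$theta)), 1e-3)
  # MLE counts the noise SD as one extra parameter
  expect_equal(f2$aic - f1$aic, 2)
})

test_that("AIC penalty arithmetic separates equal-likelihood fits", {
  f6 <- structure(list(aic = 100, converged = TRUE), class = "sn_fit")
  expect_equal(aic(f6), 100)
  # identical RSS/n, k = 6 vs k = 12 -> difference exactly 12
  n <- 990; rss <- 3.2
  a6 <- n * log(rss / n) + 2 * 6 + n * (1 + log(2 * pi))
  a12 <- n * log(rss / n) + 2 * 12 + n * (1 + log(2 * pi))
  expect_equal(a12 - a6, 12)
  bad <- structure(list(converged = FALSE), class = "sn_fit")
  expect_error(aic(bad), "unconverged")
})

test_that("model comparison handles identical fits and favors the generator", {
  tab <- data.frame(subject_id = rep(1:5, 2),
                    variant = rep(c("a", "b"), each = 5),
                    aic = rep(1:5, 2))
  cm <- compare_models(tab)
  expect_equal(cm$pairwise$mean_diff, 0)
  expect_equal(cm$pairwise$t, 0)
  expect_true(is.na(cm$pairwise$p))
  expect_error(
    compare_models(data.frame(subject_id = c(1, 2, 1),
                              variant = c("a", "a", "b"),
                              aic = 1:3)),
    "differ"
  )
})

test_that("AIC selects the generating variant on separated parameter sets", {
  set.seed(46)
  A <- rbind(c(6, 1.6, 1.0), c(2, 0.6, 0.35))
  gen <- sn_params(alpha = A, beta = c(1.69, 0.77, 0.57),
                   variant = "sn_sigdep_alpha")
  wins <- ties <- 0
  n_cohorts <- 6
  for (cix in seq_len(n_cohorts)) {
    tr <- simulate_task(3, n_blocks = 8)
    est <- simulate_estimates(tr, gen, noise = 0.15)
    fo <- fit_subjects(est, "sn_original", method = "mle")
    fa <- fit_subjects(est, "sn_sigdep_alpha", method = "mle")
    if (mean(fits_to_table(fa)$aic) < mean(fits_to_table(fo)$aic)) {
      wins <- wins + 1
    }
  }
  expect_gt(wins / n_cohorts, 0.8)
})

test_that("data generated by the original model do not reward flexibility", {
  set.seed(47)
  gen <- sn_params(alpha = c(3.69, 1.04, 0.65), beta = c(1.69, 0.77, 0.57))
  tr <- simulate_task(4, n_blocks = 8)
  est <- simulate_estimates(tr, gen, noise = 0)
  # unclipped Gaussian noise: boundary clipping induces signal-dependent
  # residual structure that genuinely rewards the doubled parameter sets
  est$P <- est$P_model + rnorm(nrow(est), 0, 0.15)
  fo <- fit_subjects(est, "sn_original", method = "mle")
  fab <- fit_subjects(est, "sn_sigdep_alphabeta", method = "mle")
  expect_lte(mean(fits_to_table(fo)$aic), mean(fits_to_table(fab)$aic))
})

test_that("fitting is invariant to trial order and drops missing periods", {
  set.seed(48)
  p <- random_params("sn_original")
  est <- sim_subject(p, n_blocks = 4, sigma = 0.1)
  f1 <- fit_subject(est)
  shuffled <- est[sample(nrow(est)), ]
  f2 <- fit_subject(shuffled)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
  miss <- simulate_missing(est, 0.05)
  f3 <- fit_subject(miss)
  expect_equal(f3$n_obs, sum(!miss$missing))
  expect_lt(max(abs(f3$theta - f1$theta)), 0.5)
})

test_that("recovery from a missing-data cohort stays within the noisy tolerance", {
  set.seed(49)
  spec <- population_spec()
  truth <- sample_subject_params(spec, 3)
  tr <- simulate_task(3, n_blocks = 11)
  est <- simulate_estimates(tr, truth, noise = 0.1)
  est <- simulate_missing(est, 0.05)
  for (s in 1:3) {
    f <- fit_subject(est[est$subject_id == s, ])
    truth_vec <- c(truth[[s]]$alpha[1, ], truth[[s]]$beta[1, ])
    expect_lt(max(abs(f$theta - truth_vec) / pmax(truth_vec, 0.3)), 0.6)
  }
})

test_that("homoscedastic residual SDs are flat across probability bins", {
  set.seed(50)
  p <- sn_params(alpha = c(3.69, 1.04, 0.65), beta = c(1.69, 0.77, 0.57))
  tr <- simulate_task(1, n_blocks = 11)
  base <- simulate_estimates(tr, p, noise = 0)
  est <- base
  est$P <- base$P_model + rnorm(nrow(base), 0, 0.1)  # unclipped
  f <- fit_subject(est)
  pred <- base$P_model
  bins <- residual_sd_by_bin(est$P, pred)
  expect_true(all(abs(bins$sd[bins$n > 30] - 0.1) < 0.03))
  # indexing by observed probability is available and changes the split
  bins_obs <- residual_sd_by_bin(est$P, pred, by = "observed")
  expect_false(identical(bins$n, bins_obs$n))
})
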