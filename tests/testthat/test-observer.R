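test_that("single-period posteriors match hand-derived values", {
  expect_equal(bayesian_posterior("blue", q = 0.1, d = 9), 0.5)
  expect_equal(bayesian_posterior("red", q = 0.1, d = 9), 1 / 82)
  # weighted observer: odds = (0.0369/0.9631) * 1.5^1.69
  odds <- (0.0369 / 0.9631) * 1.5^1.69
  expect_equal(system_neglect_posterior("blue", 0.01, 1.5, 3.69, 1.69),
               odds / (1 + odds))
})

test_that("uninformative signals reduce the posterior to the prior", {
  q <- 0.07
  r <- c(1, 0, 1, 1, 0)
  expect_equal(bayesian_posterior(r, q, 1), 1 - (1 - q)^(1:5))
  # beta = 0 ignores signals: distorted prior only
  expect_equal(system_neglect_posterior(r, 0.05, 9, alpha = 2, beta = 0),
               1 - (1 - 0.1)^(1:5))
})

test_that("no change is possible at q = 0 and certain at q = 1", {
  r <- c(0, 1, 0)
  expect_equal(bayesian_posterior(r, 0, 3), c(0, 0, 0))
  expect_equal(posterior_filter(r, 0, 3), c(0, 0, 0))
  expect_equal(bayesian_posterior(r, 1, 3), c(1, 1, 1))
  expect_equal(posterior_filter(r, 1, 3), c(1, 1, 1))
})

test_that("closed form, recursive filter, and enumeration agree", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    T <- sample(1:12, 1)
    r <- rbinom(T, 1, runif(1, 0.2, 0.8))
    q <- runif(1, 0.001, 0.5)
    d <- runif(1, 1, 12)
    a <- bayesian_posterior(r, q, d)
    b <- posterior_filter(r, q, d)
    ce <- posterior_enumerate(r, q, d)
    worst <- max(worst, abs(a - b), abs(a - ce), abs(b - ce))
  }
  expect_lt(worst, 1e-10)
  # the oracle wrapper runs without raising its consistency error
  expect_silent(posterior_oracle(c(0, 1, 0, 0), 0.05, 3))
})

test_that("mixture weights over shift times normalize to one", {
  for (q in c(1e-4, 0.01, 0.1, 0.5, 0.99, 1)) {
    for (t in c(1, 2, 5, 10, 50)) {
      j <- seq_len(t)
      w <- q * (1 - q)^(j - 1) / (1 - (1 - q)^t)
      expect_lt(abs(sum(w) - 1), 1e-12)
    }
  }
})

test_that("the weighted observer with unit weights reproduces Bayes", {
  set.seed(55)
  for (i in 1:50) {
    T <- sample(1:10, 1)
    r <- rbinom(T, 1, 0.5)
    q <- runif(1, 0.005, 0.3)
    d <- runif(1, 1, 9)
    expect_lt(max(abs(system_neglect_posterior(r, q, d, 1, 1) -
                      bayesian_posterior(r, q, d))), 1e-12)
  }
})

test_that("posteriors stay in [0, 1] and rise with d on all-blue histories", {
  set.seed(66)
  for (i in 1:50) {
    T <- sample(1:10, 1)
    r <- rbinom(T, 1, 0.5)
    P <- bayesian_posterior(r, runif(1, 0, 0.5), runif(1, 1, 9))
    expect_true(all(P >= 0 & P <= 1))
  }
  blue <- rep(0, 8)
  q <- 0.05
  P_low <- bayesian_posterior(blue, q, 2)
  P_high <- bayesian_posterior(blue, q, 6)
  expect_true(all(P_high >= P_low))
})

test_that("weighted posterior matches an independent naive reimplementation", {
  set.seed(77)
  worst <- 0
  for (i in 1:200) {
    T <- sample(1:10, 1)
    r <- rbinom(T, 1, 0.5)
    q <- runif(1, 0.005, 0.2)
    d <- runif(1, 1.1, 9)
    a <- runif(1, 0.1, min(4, 0.9 / q))
    b <- runif(1, -2, 3)
    worst <- max(worst, abs(system_neglect_posterior(r, q, d, a, b) -
                            naive_sn_posterior(r, q, d, a, b)))
  }
  expect_lt(worst, 1e-10)
})

test_that("signal-dependent selection follows the current period's signal", {
  set.seed(88)
  A <- rbind(c(4, 1.2, 0.8), c(2, 0.7, 0.4))
  B <- rbind(c(1.8, 0.9, 0.6), c(1.2, 0.6, 0.4))
  p_dep <- sn_params(alpha = A, beta = B, variant = "sn_sigdep_alphabeta")
  # degenerate doubling: both classes equal -> identical to the original model
  p_same <- sn_params(alpha = rbind(A[1, ], A[1, ]),
                      beta = rbind(B[1, ], B[1, ]),
                      variant = "sn_sigdep_alphabeta")
  p_orig <- sn_params(alpha = A[1, ], beta = B[1, ])
  r_mixed <- c(0, 1, 1, 0, 1, 0)
  expect_equal(sn_posterior_trial(r_mixed, 2, 3, p_same),
               sn_posterior_trial(r_mixed, 2, 3, p_orig))
  # all-blue history only ever selects the consistent set
  r_blue <- rep(0, 6)
  p_cons <- sn_params(alpha = A[1, ], beta = B[1, ])
  expect_equal(sn_posterior_trial(r_blue, 1, 1, p_dep),
               sn_posterior_trial(r_blue, 1, 1, p_cons))
  # mixed history with distinct sets differs from the original model and
  # matches the naive per-period selection oracle
  got <- sn_posterior_trial(r_mixed, 3, 2, p_dep)
  expect_false(isTRUE(all.equal(got, sn_posterior_trial(r_mixed, 3, 2, p_orig))))
  want <- naive_sn_posterior(r_mixed, q_levels()[3], d_levels()[2],
                             alpha = A[, 3], beta = B[, 2])
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("intertemporal prior log odds match the printed expression", {
  expect_equal(prior_log_odds(0.5, 1), 0)
  expect_equal(prior_log_odds(0.1, 1), log(1 / 9))
  for (q in c(0.01, 0.05, 0.1, 0.6)) {
    v <- prior_log_odds(q, 1:10)
    expect_true(all(diff(v) > 0))
  }
  expect_error(prior_log_odds(0, 1), "strictly inside")
  expect_error(prior_log_odds(1, 2), "strictly inside")
})

test_that("parameter domain violations are rejected", {
  expect_error(bayesian_posterior(c(0, 1), -0.1, 3), "\\[0, 1\\]")
  expect_error(bayesian_posterior(c(0, 1), 0.1, 0.9), ">= 1")
  expect_error(system_neglect_posterior(c(0, 1), 0.1, 3, alpha = 11),
               "alpha \\* q")
  expect_error(sn_params(alpha = c(-1, 1, 1)), ">= 0")
  expect_error(sn_params(alpha = c(1, 1, 11)), "alpha \\* q")
})

test_that("variant parameter counts follow the model family", {
  expect_equal(n_free_params("bayes"), 0L)
  expect_equal(n_free_params("sn_original"), 6L)
  expect_equal(n_free_params("sn_sigdep_beta"), 9L)
  expect_equal(n_free_params("sn_sigdep_alpha"), 9L)
  expect_equal(n_free_params("sn_sigdep_alphabeta"), 12L)
  expect_error(sn_params(alpha = c(1, 1, 1), variant = "sn_sigdep_alpha"),
               "2x3")
})
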