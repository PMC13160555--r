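#' @keywords internal
#' Precompute per-condition design structures for fast repeated prediction.
#'
#' For every condition the posterior at (trial, period t) is
#' prior_odds(alpha*q, t) * sum_j W[t, j] * d^(beta * E[t, j]) with the
#' integer exponent E and mixture weights W fixed by the data. Stacking all
#' (trial, period) rows of a condition lets one parameter evaluation be two
#' vectorized matrix operations per condition.
prepare_fit_data <- function(estimates, q = q_levels(), d = d_levels()) {
  if (length(unique(estimates$subject_id)) != 1L) {
    stop("`estimates` must contain exactly one subject; see fit_subjects()",
         call. = FALSE)
  }
  Tm <- max(estimates$period)
  evals <- -Tm:Tm
  conds <- list()
  for (i in seq_along(q)) {
    for (j in seq_along(d)) {
      sub <- estimates[estimates$q_level == i & estimates$d_level == j, ,
                       drop = FALSE]
      if (nrow(sub) == 0) next
      key <- interaction(sub$block, sub$trial, drop = TRUE)
      Wbase <- matrix(0, Tm, Tm)
      for (t in seq_len(Tm)) {
        jj <- seq_len(t)
        Wbase[t, jj] <- q[i] * (1 - q[i])^(jj - 1) / (1 - (1 - q[i])^t)
      }
      idx_l <- list(); w_l <- list(); t_l <- list(); cls_l <- list()
      y_l <- list(); keep_l <- list()
      for (rows in split(seq_len(nrow(sub)), key)) {
        rows <- rows[order(sub$period[rows])]
        r <- signal_code(sub$signal[rows])
        Tt <- length(r)
        cs <- c(0, cumsum(r))
        E <- matrix(0L, Tt, Tm)
        for (t in seq_len(Tt)) {
          jj <- seq_len(t)
          E[t, jj] <- (t + 1L - jj) - 2L * (cs[t + 1L] - cs[jj])
        }
        idx_l[[length(idx_l) + 1L]] <- E + Tm + 1L
        w_l[[length(w_l) + 1L]] <- Wbase[seq_len(Tt), , drop = FALSE]
        t_l[[length(t_l) + 1L]] <- seq_len(Tt)
        cls_l[[length(cls_l) + 1L]] <- ifelse(r == 1L, 2L, 1L)
        y_l[[length(y_l) + 1L]] <- sub$P[rows]
        keep_l[[length(keep_l) + 1L]] <- !sub$missing[rows]
      }
      conds[[length(conds) + 1L]] <- list(
        q_level = i, d_level = j, q = q[i], d = d[j],
        IDX = do.call(rbind, idx_l), W = do.call(rbind, w_l),
        tvec = unlist(t_l), cls = unlist(cls_l), y = unlist(y_l),
        keep = unlist(keep_l), evals = evals
      )
    }
  }
  structure(list(conds = conds, q = q, d = d, Tm = Tm,
                 n_obs = sum(vapply(conds, function(cc) sum(cc$keep), 0))),
            class = "sn_fit_data")
}

predict_condition <- function(cond, a_cons, a_incon, b_cons, b_incon) {
  aq <- ifelse(cond$cls == 1L, a_cons, a_incon) * cond$q
  surv <- (1 - aq)^cond$tvec
  po <- (1 - surv) / surv
  ld <- log(cond$d)
  if (b_cons == b_incon) {
    pw <- exp(ld * b_cons * cond$evals)
    V <- matrix(pw[cond$IDX], nrow(cond$IDX))
  } else {
    V <- matrix(0, nrow(cond$IDX), ncol(cond$IDX))
    i1 <- cond$cls == 1L
    if (any(i1)) {
      pw <- exp(ld * b_cons * cond$evals)
      V[i1, ] <- matrix(pw[cond$IDX[i1, , drop = FALSE]], sum(i1))
    }
    if (any(!i1)) {
      pw <- exp(ld * b_incon * cond$evals)
      V[!i1, ] <- matrix(pw[cond$IDX[!i1, , drop = FALSE]], sum(!i1))
    }
  }
  odds <- po * rowSums(cond$W * V)
  odds / (1 + odds)
}

theta_layout <- function(variant, q, eps = 1e-6) {
  dep_a <- variant %in% c("sn_sigdep_alpha", "sn_sigdep_alphabeta")
  dep_b <- variant %in% c("sn_sigdep_beta", "sn_sigdep_alphabeta")
  na <- if (dep_a) 6L else 3L
  nb <- if (dep_b) 6L else 3L
  a_upper <- (1 - eps) / q
  list(
    dep_a = dep_a, dep_b = dep_b, na = na, nb = nb,
    names = c(paste0("alpha", if (dep_a) c("_cons", "_incon") else "",
                     rep(1:3, times = if (dep_a) 2 else 1)),
              paste0("beta", if (dep_b) c("_cons", "_incon") else "",
                     rep(1:3, times = if (dep_b) 2 else 1))),
    lower = c(rep(0, na), rep(-10, nb)),
    upper = c(rep(a_upper, if (dep_a) 2 else 1), rep(10, nb))
  )
}

theta_to_matrices <- function(theta, layout) {
  if (layout$dep_a) {
    A <- rbind(theta[1:3], theta[4:6])
  } else {
    A <- rbind(theta[1:3], theta[1:3])
  }
  bb <- theta[(layout$na + 1):(layout$na + layout$nb)]
  if (layout$dep_b) {
    B <- rbind(bb[1:3], bb[4:6])
  } else {
    B <- rbind(bb, bb)
  }
  list(A = A, B = B)
}

predict_fit_data <- function(fd, theta, layout) {
  m <- theta_to_matrices(theta, layout)
  unlist(lapply(fd$conds, function(cond) {
    predict_condition(cond, m$A[1, cond$q_level], m$A[2, cond$q_level],
                      m$B[1, cond$d_level], m$B[2, cond$d_level])
  }))
}

default_starts <- function(layout, n_random = 3L) {
  ones <- rep(1, layout$na + layout$nb)
  gm_a <- rep(c(3.69, 1.04, 0.65), length.out = layout$na)
  gm_b <- rep(c(1.69, 0.77, 0.57), length.out = layout$nb)
  starts <- list(ones, c(gm_a, gm_b))
  for (k in seq_len(n_random)) {
    a <- exp(stats::runif(layout$na, log(0.2), log(4)))
    b <- stats::runif(layout$nb, -0.5, 2.5)
    starts[[length(starts) + 1L]] <- c(a, b)
  }
  starts
}

#' Fit an observer model to one subject's probability estimates
#'
#' Minimizes the sum of squared deviations between the subject's per-period
#' probability estimates and the model posterior over all non-missing
#' periods (Levenberg-Marquardt with box constraints: alpha in
#' \[0, (1-eps)/q\] per level, beta in \[-10, 10\]). Multi-start policy:
#' all-ones, the group-mean parameters, and `n_random_starts` random draws;
#' the best residual sum of squares wins, ties broken by start order.
#'
#' The `"mle"` method additionally estimates the Gaussian response-noise SD.
#' Because the Gaussian likelihood in the location parameters is maximized
#' by the least-squares solution, the MLE is computed by profiling:
#' sigma_hat^2 = RSS/n (floored at 1e-4), with the log-likelihood and AIC
#' following from the profile.
#'
#' @param estimates single-subject long table with columns `q_level`,
#'   `d_level`, `block`, `trial`, `period`, `signal`, `P`, `missing`
#'   (see [simulate_estimates()]).
#' @param variant one of [sn_variants()] except `"bayes"` (which has no
#'   free parameters; use [model_posterior()] directly).
#' @param method `"nls"` (nonlinear least squares) or `"mle"` (adds the
#'   noise parameter by profiling).
#' @param n_random_starts random multi-starts after the two fixed starts.
#' @param q,d system-parameter levels.
#' @return object of class `sn_fit`: fitted [sn_params()], `theta`, `rss`,
#'   `n_obs`, `residuals`, `sigma_hat`, `logLik`, `aic`, `converged`,
#'   `variant`, `method`.
#' @export
fit_subject <- function(estimates, variant = "sn_original",
                        method = c("nls", "mle"), n_random_starts = 3L,
                        q = q_levels(), d = d_levels()) {
  variant <- match.arg(variant, setdiff(sn_variants(), "bayes"))
  method <- match.arg(method)
  fd <- if (inherits(estimates, "sn_fit_data")) estimates
        else prepare_fit_data(estimates, q, d)
  layout <- theta_layout(variant, fd$q)
  keep <- unlist(lapply(fd$conds, `[[`, "keep"))
  y <- unlist(lapply(fd$conds, `[[`, "y"))[keep]
  n <- length(y)
  k <- n_free_params(variant)
  if (n <= k) stop("not enough non-missing observations to fit ", variant,
                   call. = FALSE)
  resid_fn <- function(theta) y - predict_fit_data(fd, theta, layout)[keep]
  best <- NULL
  convs <- logical(0)
  for (s in seq_along(starts <- default_starts(layout, n_random_starts))) {
    th0 <- pmin(pmax(starts[[s]], layout$lower), layout$upper)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = th0, lower = layout$lower, upper = layout$upper,
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                             ptol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) { convs <- c(convs, FALSE); next }
    conv <- res$info %in% 1:4
    convs <- c(convs, conv)
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(theta = res$par, rss = rss, info = res$info,
                   message = res$message, start = s, fvec = res$fvec)
    }
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, variant = variant,
                          method = method, n_obs = n,
                          message = "all starts failed"), class = "sn_fit"))
  }
  m <- theta_to_matrices(best$theta, layout)
  a_par <- if (layout$dep_a) m$A else m$A[1, ]
  b_par <- if (layout$dep_b) m$B else m$B[1, ]
  sigma_hat <- max(sqrt(best$rss / n), 1e-4)
  logLik <- -n / 2 * log(2 * pi * sigma_hat^2) -
    best$rss / (2 * sigma_hat^2)
  aic <- if (method == "mle") 2 * (k + 1) - 2 * logLik
         else n * log(best$rss / n) + 2 * k + n * (1 + log(2 * pi))
  pars <- sn_params(alpha = a_par, beta = b_par, variant = variant,
                    sigma = if (method == "mle") sigma_hat else NULL,
                    q = fd$q, d = fd$d)
  structure(
    list(params = pars, theta = stats::setNames(best$theta, layout$names),
         variant = variant, method = method, rss = best$rss, n_obs = n,
         residuals = best$fvec, sigma_hat = sigma_hat, logLik = logLik,
         aic = aic, k = k, converged = any(convs), start_used = best$start,
         boundary_hit = any(abs(best$theta - layout$lower) < 1e-8 |
                            abs(best$theta - layout$upper) < 1e-8)),
    class = "sn_fit"
  )
}

#' @export
print.sn_fit <- function(x, ...) {
  cat("<sn_fit> variant:", x$variant, " method:", x$method, "\n")
  if (!isTRUE(x$converged)) {
    cat("NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat("n_obs:", x$n_obs, " RSS:", signif(x$rss, 6),
      " sigma_hat:", signif(x$sigma_hat, 4), " AIC:", signif(x$aic, 6), "\n")
  print(x$params)
  invisible(x)
}

#' Fit every subject in a long estimates table
#'
#' @inheritParams fit_subject
#' @param estimates multi-subject long table.
#' @return named list of `sn_fit` objects, one per subject.
#' @export
fit_subjects <- function(estimates, variant = "sn_original",
                         method = c("nls", "mle"), n_random_starts = 3L,
                         q = q_levels(), d = d_levels()) {
  subjects <- sort(unique(estimates$subject_id))
  fits <- lapply(subjects, function(s) {
    fit_subject(estimates[estimates$subject_id == s, , drop = FALSE],
                variant, method, n_random_starts, q, d)
  })
  names(fits) <- subjects
  fits
}

#' Akaike Information Criterion of a fit
#'
#' For the MLE path, `AIC = 2(k+1) - 2 logL` with the response-noise SD
#' counted as a parameter. For the least-squares path the Gaussian profile
#' form `n log(RSS/n) + 2k + n(1 + log 2pi)` is used; the constant is
#' included so values are comparable across paths. Lower is better.
#'
#' @param fit an `sn_fit`.
#' @return AIC value (scalar).
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "sn_fit"))
  if (!isTRUE(fit$converged)) {
    stop("AIC undefined for an unconverged fit", call. = FALSE)
  }
  fit$aic
}

#' Compare model variants across subjects by AIC
#'
#' @param fit_table data.frame with columns `subject_id`, `variant`, `aic`
#'   (one row per subject per variant; see [fits_to_table()]), or a named
#'   list of per-variant fit lists as returned by [fit_subjects()].
#' @return list with `group` (per-variant mean AIC and SEM) and `pairwise`
#'   (per pair: mean AIC difference and paired two-tailed t-test). A pair
#'   with identical AICs across all subjects yields `t = 0`, `p = NA` and
#'   is reported as no difference.
#' @export
compare_models <- function(fit_table) {
  if (is.list(fit_table) && !is.data.frame(fit_table)) {
    fit_table <- do.call(rbind, lapply(names(fit_table), function(v) {
      fits_to_table(fit_table[[v]], variant = v)
    }))
  }
  stopifnot(all(c("subject_id", "variant", "aic") %in% names(fit_table)))
  wide <- stats::reshape(
    fit_table[c("subject_id", "variant", "aic")],
    idvar = "subject_id", timevar = "variant", direction = "wide"
  )
  if (anyNA(wide)) stop("subject sets differ across variants", call. = FALSE)
  variants <- sub("^aic\\.", "", names(wide)[-1])
  group <- data.frame(
    variant = variants,
    mean_aic = colMeans(wide[-1]),
    sem_aic = apply(wide[-1], 2, stats::sd) / sqrt(nrow(wide)),
    row.names = NULL
  )
  pairs <- utils::combn(seq_along(variants), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(cix) {
    i <- pairs[1, cix]; j <- pairs[2, cix]
    dif <- wide[[i + 1]] - wide[[j + 1]]
    if (all(abs(dif) < 1e-12)) {
      return(data.frame(variant1 = variants[i], variant2 = variants[j],
                        mean_diff = 0, t = 0, df = length(dif) - 1,
                        p = NA_real_))
    }
    tt <- stats::t.test(wide[[i + 1]], wide[[j + 1]], paired = TRUE)
    data.frame(variant1 = variants[i], variant2 = variants[j],
               mean_diff = mean(dif), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  list(group = group, pairwise = do.call(rbind, pw))
}

#' Tidy table of fitted parameters and criteria
#'
#' @param fits list of `sn_fit` objects named by subject (see
#'   [fit_subjects()]).
#' @param variant optional variant label override.
#' @return data.frame with one row per subject: `subject_id`, `variant`,
#'   `rss`, `n_obs`, `sigma_hat`, `aic`, `converged`, and one column per
#'   parameter.
#' @export
fits_to_table <- function(fits, variant = NULL) {
  rows <- lapply(names(fits), function(s) {
    f <- fits[[s]]
    base <- data.frame(subject_id = s,
                       variant = if (is.null(variant)) f$variant else variant,
                       rss = f$rss, n_obs = f$n_obs,
                       sigma_hat = f$sigma_hat, aic = f$aic,
                       converged = f$converged)
    cbind(base, as.data.frame(as.list(f$theta)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
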