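#' Cross- and within-family parameter correlation matrices
#'
#' Pearson correlations of subject-level weighting parameters: the 3x3
#' cross-family matrix (alpha_i vs beta_j), and the 3x3 within-family
#' matrices for alpha and for beta, with pairwise p-values. In the human
#' cohort the cross-family entries are near zero while the within-family
#' entries are positive: how strongly a person distorts the transition
#' probability says little about how they distort diagnosticity, but
#' distortion is consistent across levels of the same parameter.
#'
#' @param alpha n x 3 matrix of per-subject alpha estimates (columns =
#'   levels), or a list of [sn_params()] from which both matrices are taken.
#' @param beta n x 3 matrix of per-subject beta estimates.
#' @return list with `cross`, `within_alpha`, `within_beta`; each a list of
#'   matrices `r` and `p`. Constant columns yield `NA` entries with a
#'   warning.
#' @export
parameter_correlation_matrix <- function(alpha, beta = NULL) {
  if (is.list(alpha) && !is.matrix(alpha) && is.null(beta)) {
    params <- alpha
    alpha <- t(vapply(params, function(p) p$alpha[1, ], numeric(3)))
    beta <- t(vapply(params, function(p) p$beta[1, ], numeric(3)))
  }
  stopifnot(is.matrix(alpha), is.matrix(beta), ncol(alpha) == 3,
            ncol(beta) == 3, nrow(alpha) == nrow(beta))
  if (nrow(alpha) < 4) stop("need at least 4 subjects", call. = FALSE)
  pair_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant column: correlation undefined", call. = FALSE)
      return(c(NA_real_, NA_real_))
    }
    ct <- stats::cor.test(x, y)
    c(unname(ct$estimate), ct$p.value)
  }
  mat_pair <- function(X, Y, xn, yn) {
    r <- p <- matrix(NA_real_, 3, 3,
                     dimnames = list(paste0(xn, 1:3), paste0(yn, 1:3)))
    for (i in 1:3) for (j in 1:3) {
      rp <- pair_cor(X[, i], Y[, j])
      r[i, j] <- rp[1]; p[i, j] <- rp[2]
    }
    list(r = r, p = p)
  }
  list(cross = mat_pair(alpha, beta, "alpha", "beta"),
       within_alpha = mat_pair(alpha, alpha, "alpha", "alpha"),
       within_beta = mat_pair(beta, beta, "beta", "beta"))
}

#' Meng-style z test for two dependent correlations
#'
#' Tests the difference between two Pearson correlations `r1 = cor(x, y1)`
#' and `r2 = cor(x, y2)` that share the variable `x`, given the correlation
#' `r_x = cor(y1, y2)` between the non-shared variables:
#'
#' z = (atanh(r1) - atanh(r2)) * sqrt((N - 3) / (2 (1 - r_x) h)),
#' with rbar2 = (r1^2 + r2^2)/2, f = (1 - r_x) / (2 (1 - rbar2)) capped at
#' 1, and h = 1 + rbar2 / (1 - rbar2) * (1 - f).
#'
#' @param r1,r2 the two dependent correlations (|r| < 1).
#' @param r_x correlation between the two non-shared variables.
#' @param N number of subjects (>= 4).
#' @return list with `z`, `p_one_tailed` (upper tail for `z > 0`),
#'   `p_two_tailed`, and the intermediate `f`, `h`.
#' @examples
#' meng_z(0.5, 0.0, r_x = 0.3, N = 30)$z  # ~2.315
#' @export
meng_z <- function(r1, r2, r_x, N) {
  if (N < 4) stop("N must be >= 4", call. = FALSE)
  if (any(abs(c(r1, r2)) >= 1)) stop("|r| must be < 1", call. = FALSE)
  guard <- 1 - 1e-12
  z1 <- atanh(pmin(pmax(r1, -guard), guard))
  z2 <- atanh(pmin(pmax(r2, -guard), guard))
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min((1 - r_x) / (2 * (1 - rbar2)), 1)
  h <- 1 + rbar2 / (1 - rbar2) * (1 - f)
  z <- (z1 - z2) * sqrt((N - 3) / (2 * (1 - r_x) * h))
  list(z = z,
       p_one_tailed = stats::pnorm(abs(z), lower.tail = FALSE),
       p_two_tailed = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       f = f, h = h)
}

fast_cor <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Subject-wise bootstrap for a difference of dependent correlations
#'
#' Resamples subjects (joint rows of `x`, `y1`, `y2`) with replacement and
#' recomputes `cor(x, y1) - cor(x, y2)` in each resample to estimate the
#' distribution of the difference. The one-tailed p-value is the
#' add-one-corrected proportion of resamples in which the difference falls
#' on the opposite side of zero from the observed difference (a degenerate
#' resample with a constant column is redrawn and counted).
#'
#' @param x,y1,y2 equal-length subject vectors (n >= 4).
#' @param n_boot number of resamples (default 100000, minimum 1000).
#' @param two_tailed also report the two-tailed p (doubled, capped at 1)?
#' @param seed optional integer seed.
#' @return list of class `boot_corr_diff`: `observed` (r1, r2, difference),
#'   `p_one_tailed`, `p_two_tailed`, `boot_diffs` summary (quantiles),
#'   `n_boot`, `n_degenerate`, `seed`.
#' @export
bootstrap_corr_diff <- function(x, y1, y2, n_boot = 100000L,
                                two_tailed = FALSE, seed = NULL) {
  n <- length(x)
  stopifnot(length(y1) == n, length(y2) == n, n >= 4)
  if (n_boot < 1000) stop("n_boot must be >= 1000", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r1 <- fast_cor(x, y1); r2 <- fast_cor(x, y2)
  obs <- r1 - r2
  diffs <- numeric(n_boot)
  n_degen <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      xs <- x[idx]
      if (stats::sd(xs) > 0 && stats::sd(y1[idx]) > 0 &&
          stats::sd(y2[idx]) > 0) break
      n_degen <- n_degen + 1L
    }
    diffs[b] <- fast_cor(xs, y1[idx]) - fast_cor(xs, y2[idx])
  }
  # one-tailed: evidence against the observed sign of the difference
  wrong_side <- if (obs >= 0) sum(diffs <= 0) else sum(diffs >= 0)
  p1 <- (wrong_side + 1) / (n_boot + 1)
  structure(
    list(observed = c(r1 = r1, r2 = r2, diff = obs),
         p_one_tailed = p1,
         p_two_tailed = if (two_tailed) min(2 * p1, 1) else NA_real_,
         boot_quantiles = stats::quantile(diffs,
                                          c(0.025, 0.25, 0.5, 0.75, 0.975)),
         n_boot = n_boot, n_degenerate = n_degen, seed = seed),
    class = "boot_corr_diff"
  )
}

#' @export
print.boot_corr_diff <- function(x, ...) {
  cat("<boot_corr_diff> r1 =", round(x$observed["r1"], 4),
      " r2 =", round(x$observed["r2"], 4),
      " diff =", round(x$observed["diff"], 4), "\n")
  cat("one-tailed p =", signif(x$p_one_tailed, 4),
      " (", x$n_boot, "resamples )\n")
  invisible(x)
}
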