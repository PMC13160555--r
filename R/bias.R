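#' Index of Overreaction
#'
#' Quantifies over- and underreaction to change as the difference between
#' the observed belief revision and the Bayesian belief revision,
#' `IO = dP_t - dP_t^B` with `dP_t = P_t - P_{t-1}` over periods
#' t = 2..T. `IO > 0` is overreaction, `IO < 0` underreaction; an observer
#' reproducing the Bayesian posterior has IO identically zero. Period-level
#' IO is averaged within condition per subject, then across subjects with
#' equal weight.
#'
#' @param data long table with columns `subject_id`, `block`, `trial`,
#'   `q_level`, `d_level`, `period`, observed estimates in `P`, and the
#'   Bayesian posterior in `P_bayes` (use [add_bayesian_posterior()] to
#'   append it from the signals). Missing periods (`NA` in `P`) and the
#'   periods adjacent to them are dropped from the revision.
#' @param include_first also count the first-period revision, taking the
#'   period-0 belief as 0 (every trial starts in the red regime with
#'   certainty)? Default FALSE: the revision window is t = 2..T. Because the
#'   equal-weight period mean of `dP - dP^B` telescopes to the endpoint
#'   differences, the t = 2..T convention makes the noiseless model's IO in
#'   the corner conditions a near-degenerate contrast of first- and
#'   last-period beliefs; including the first revision measures the full
#'   belief path from the known start and resolves the corner-cell signs.
#' @return list of class `io_summary`: `by_subject` (mean IO per subject per
#'   condition), `by_condition` (grand mean and SEM per condition).
#' @export
index_of_overreaction <- function(data, include_first = FALSE) {
  need <- c("subject_id", "block", "trial", "q_level", "d_level", "period",
            "P", "P_bayes")
  if (!all(need %in% names(data))) {
    stop("`data` must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  key <- interaction(data$subject_id, data$block, data$trial, drop = TRUE)
  rows <- list()
  for (idx in split(seq_len(nrow(data)), key)) {
    idx <- idx[order(data$period[idx])]
    if (length(idx) < 2) next
    P <- data$P[idx]; PB <- data$P_bayes[idx]
    io <- if (include_first) diff(c(0, P)) - diff(c(0, PB))
          else diff(P) - diff(PB)
    keep <- !is.na(io)
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = data$subject_id[idx][1],
      q_level = data$q_level[idx][1], d_level = data$d_level[idx][1],
      io_sum = sum(io[keep]), n = sum(keep)
    )
  }
  per <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(io_sum, n) ~ subject_id + q_level + d_level,
                          per, sum)
  agg$mean_io <- agg$io_sum / agg$n
  by_subject <- agg[c("subject_id", "q_level", "d_level", "mean_io")]
  grand <- stats::aggregate(mean_io ~ q_level + d_level, by_subject,
                            function(x) c(mean = mean(x),
                                          sem = stats::sd(x) / sqrt(length(x))))
  by_condition <- data.frame(q_level = grand$q_level,
                             d_level = grand$d_level,
                             mean_io = grand$mean_io[, "mean"],
                             sem_io = grand$mean_io[, "sem"])
  structure(list(by_subject = by_subject, by_condition = by_condition),
            class = "io_summary")
}

#' @export
print.io_summary <- function(x, ...) {
  cat("<io_summary> mean Index of Overreaction by condition\n")
  print(x$by_condition, row.names = FALSE)
  invisible(x)
}

#' Append the Bayesian posterior to a trial table
#'
#' @param trials long trial table with `signal`, `q`, `d` and trial keys.
#' @return `trials` with a `P_bayes` column.
#' @export
add_bayesian_posterior <- function(trials) {
  trials$P_bayes <- model_posterior(trials, sn_params(variant = "bayes"))
  trials
}

#' Behavioral sensitivity slope
#'
#' Sensitivity of the subjectively weighted system parameter to its
#' objective level, estimated by OLS with intercept over the three levels.
#' For the diagnosticity family the weighted value is `beta_j * ln(d_j)`
#' regressed on `ln(d_j)`; for the transition-probability family it is the
#' effective transition probability `alpha_i * q_i` regressed on `q_i`.
#' Bayesian weights (all 1) give slope 1; complete neglect (constant
#' weighted value) gives slope 0.
#'
#' @param params an [sn_params()] object, or a length-3 numeric vector of
#'   weights for the chosen family.
#' @param family `"d"` (diagnosticity) or `"q"` (transition probability).
#' @param q,d levels used when `params` is a bare vector.
#' @return list with `gamma` (slope), `intercept`, `weighted` (the three
#'   weighted values), `x` (the regressor values), `family`.
#' @examples
#' behavioral_slope(sn_params(), family = "d")$gamma  # 1
#' @export
behavioral_slope <- function(params, family = c("d", "q"),
                             q = q_levels(), d = d_levels()) {
  family <- match.arg(family)
  if (inherits(params, "sn_params")) {
    w <- if (family == "d") params$beta[1, ] else params$alpha[1, ]
    q <- params$q; d <- params$d
  } else {
    stopifnot(length(params) == 3)
    w <- as.numeric(params)
  }
  if (any(!is.finite(w))) stop("non-finite parameters", call. = FALSE)
  x <- if (family == "d") log(d) else q
  yv <- w * x
  fit <- stats::lm(yv ~ x)
  list(gamma = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       weighted = yv, x = x, family = family)
}

#' Position of a cohort's slopes between complete neglect and Bayesian
#'
#' One-sample two-tailed t-tests of the behavioral slopes against 0
#' (complete neglect), 1 (Bayesian), and 0.5 (the midpoint). A mean slope
#' significantly below 0.5 places the cohort closer to complete neglect than
#' to Bayesian updating.
#'
#' @param gammas numeric vector of included subjects' slopes (>= 2 values).
#' @return data.frame with one row per reference value: `mu`, `mean_gamma`,
#'   `t`, `df`, `p`.
#' @export
neglect_position_tests <- function(gammas) {
  gammas <- gammas[!is.na(gammas)]
  if (length(gammas) < 2) stop("need at least 2 subjects", call. = FALSE)
  do.call(rbind, lapply(c(0, 0.5, 1), function(mu) {
    tt <- stats::t.test(gammas, mu = mu)
    data.frame(mu = mu, mean_gamma = mean(gammas),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
}

#' Flag outlier slopes
#'
#' Subjects whose slope falls outside `bounds` are flagged excluded (never
#' silently dropped). The default bounds (-0.5, 1.5) keep slopes between and
#' near the complete-neglect (0) and Bayesian (1) boundaries while excluding
#' clearly out-of-range cases such as a slope of 2.
#'
#' @param gammas numeric vector of slopes.
#' @param bounds length-2 numeric (low, high).
#' @return data.frame with `gamma`, `included`; excluded subjects are also
#'   reported via `message()`.
#' @export
exclude_outlier_slopes <- function(gammas, bounds = c(-0.5, 1.5)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  included <- gammas >= bounds[1] & gammas <= bounds[2]
  if (any(!included)) {
    message(sum(!included), " slope(s) outside [", bounds[1], ", ",
            bounds[2], "] flagged excluded")
  }
  data.frame(subject = seq_along(gammas), gamma = gammas,
             included = included)
}

#' Action-handedness code of a two-digit probability entry
#'
#' Estimates were entered as two digits on a ten-button pad: digits 1-5 are
#' pressed with the left hand, digits 6-9 and 0 with the right. The code is
#' -1 when both presses are left-handed, +1 when both are right-handed, and
#' 0 for a mixed entry.
#'
#' @param P probability estimates in \[0, 1\], expressible as hundredths
#'   below 1 (an entry has exactly two digits).
#' @return integer vector in \{-1, 0, 1\}.
#' @examples
#' handedness_code(c(0.23, 0.75, 0.90))  # -1 0 1
#' @export
handedness_code <- function(P) {
  cents <- round(P * 100)
  if (any(abs(P * 100 - cents) > 1e-6) || any(cents < 0) || any(cents > 99)) {
    stop("estimate not expressible as a two-digit entry", call. = FALSE)
  }
  digit_hand <- function(dg) ifelse(dg >= 1 & dg <= 5, -1L, 1L)
  tens <- cents %/% 10
  ones <- cents %% 10
  h <- digit_hand(tens) + digit_hand(ones)
  as.integer(h / 2)
}

#' Period-level design regressors
#'
#' Computes the per-period quantities used as parametric regressors in the
#' study's design matrices: the probability estimate `P_t`, belief revision
#' `dP_t`, certainty `|P_t - 0.5|`, the period number, the signal code `s`
#' (+1 blue = consistent with change, -1 red), the strength of change
#' evidence `s * ln(d)`, the intertemporal prior log odds
#' `ln((1-(1-q)^t)/(1-q)^t)`, and (optionally) the action-handedness code of
#' the two-digit entry.
#'
#' @param data long table with `subject_id`, `block`, `trial`, `q`, `d`,
#'   `period`, `signal`, `P`.
#' @param handedness compute the handedness code? Requires estimates
#'   expressible as two-digit entries.
#' @return `data` with columns `dP`, `certainty`, `signal_code`,
#'   `evidence_strength`, `prior_log_odds` (and `handedness`) appended.
#' @export
design_regressors <- function(data, handedness = FALSE) {
  key <- interaction(data$subject_id, data$block, data$trial, drop = TRUE)
  dP <- rep(NA_real_, nrow(data))
  for (idx in split(seq_len(nrow(data)), key)) {
    idx <- idx[order(data$period[idx])]
    dP[idx[-1]] <- diff(data$P[idx])
  }
  s <- ifelse(signal_code(data$signal) == 1L, -1L, 1L)
  out <- data
  out$dP <- dP
  out$certainty <- abs(data$P - 0.5)
  out$signal_code <- s
  out$evidence_strength <- s * log(data$d)
  out$prior_log_odds <- prior_log_odds(data$q, data$period)
  if (handedness) out$handedness <- handedness_code(data$P)
  out
}
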