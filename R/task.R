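#' Default system-parameter levels
#'
#' The task crosses three per-period transition probabilities with three
#' signal diagnosticities in a 3x3 factorial design. These helpers return the
#' default levels; every function that needs them accepts alternatives.
#'
#' @return `q_levels()` returns the three transition probabilities;
#'   `d_levels()` returns the three signal diagnosticities.
#' @examples
#' q_levels()
#' d_levels()
#' @export
q_levels <- function() c(0.01, 0.05, 0.1)

#' @rdname q_levels
#' @export
d_levels <- function() c(1.5, 3, 9)

#' Condition grid of the factorial design
#'
#' One row per cell of the transition-probability by signal-diagnosticity
#' design. `dominant_fraction` is the proportion of the dominant ball color
#' in each regime's urn, `d / (d + 1)` (0.9 for d = 9, 0.6 for d = 1.5).
#'
#' @param q numeric vector of transition-probability levels.
#' @param d numeric vector of signal-diagnosticity levels (each >= 1).
#' @return data.frame with columns `q_level`, `d_level`, `q`, `d`,
#'   `dominant_fraction`.
#' @export
condition_grid <- function(q = q_levels(), d = d_levels()) {
  check_q(q)
  check_d(d)
  g <- expand.grid(q_level = seq_along(q), d_level = seq_along(d))
  data.frame(
    q_level = g$q_level,
    d_level = g$d_level,
    q = q[g$q_level],
    d = d[g$d_level],
    dominant_fraction = d[g$d_level] / (d[g$d_level] + 1)
  )
}

check_q <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("transition probability `q` must lie in [0, 1]", call. = FALSE)
  }
  invisible(q)
}

check_d <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 1)) {
    stop("signal diagnosticity `d` must be >= 1", call. = FALSE)
  }
  invisible(d)
}

#' Generate one trial of the regime-shift task
#'
#' A trial starts in the red regime. Before every period (including the
#' first) a Bernoulli(q) draw decides whether the regime shifts to the blue
#' regime; once shifted the blue regime is absorbing and no further draws are
#' made. The signal of each period is sampled from the current regime's urn:
#' the red urn emits red with probability d/(d+1), the blue urn emits blue
#' with probability d/(d+1).
#'
#' @param q per-period transition probability in \[0, 1\].
#' @param d signal diagnosticity, >= 1.
#' @param n_periods number of periods (default 10).
#' @return list with `signals` (character, "red"/"blue"), `regime`
#'   (character, latent regime per period), `change_period` (first blue
#'   period, or `NA` if the regime never shifted), `q`, `d`, `n_periods`.
#' @examples
#' set.seed(1)
#' generate_trial(0.1, 9)
#' @export
generate_trial <- function(q, d, n_periods = 10L) {
  check_q(q)
  check_d(d)
  stopifnot(length(q) == 1L, length(d) == 1L, n_periods >= 1L)
  shift_draws <- stats::rbinom(n_periods, 1L, q)
  hit <- which(shift_draws == 1L)
  change_period <- if (length(hit)) hit[1L] else NA_integer_
  regime <- rep("red", n_periods)
  if (!is.na(change_period)) regime[change_period:n_periods] <- "blue"
  p_dom <- d / (d + 1)
  u <- stats::runif(n_periods)
  # dominant color matches the regime
  signals <- ifelse(u < p_dom, regime, ifelse(regime == "red", "blue", "red"))
  list(
    signals = signals, regime = regime, change_period = change_period,
    q = q, d = d, n_periods = as.integer(n_periods)
  )
}

#' Generate a blocked design table
#'
#' Each block presents the nine cells of the factorial design once, in
#' randomized order. The full study design is 11 blocks per subject (8 in the
#' behavioral session plus 3 in the scanner session), i.e. 99 trials and 990
#' periods.
#'
#' @param n_blocks number of blocks.
#' @param conditions condition table as from [condition_grid()].
#' @return data.frame with columns `block`, `trial` (within block),
#'   `q_level`, `d_level`, `q`, `d`.
#' @export
generate_design <- function(n_blocks, conditions = condition_grid()) {
  stopifnot(is.numeric(n_blocks), n_blocks >= 1, nrow(conditions) >= 1)
  n_blocks <- as.integer(n_blocks)
  nc <- nrow(conditions)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    ord <- sample.int(nc)
    cbind(block = b, trial = seq_len(nc),
          conditions[ord, c("q_level", "d_level", "q", "d")])
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Simulate the full task for one or more subjects
#'
#' Generates a fresh randomized design and fresh trial sequences for every
#' subject, in long (one row per period) format.
#'
#' @param n_subjects number of subjects.
#' @param n_blocks blocks per subject (default 11: the full study design).
#' @param n_periods periods per trial (default 10).
#' @param conditions condition table as from [condition_grid()].
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `subject_id`, `block`, `trial`, `q_level`,
#'   `d_level`, `q`, `d`, `period`, `signal`, `regime`, `change_period`.
#' @examples
#' head(simulate_task(1, n_blocks = 1, seed = 1))
#' @export
simulate_task <- function(n_subjects, n_blocks = 11L, n_periods = 10L,
                          conditions = condition_grid(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    design <- generate_design(n_blocks, conditions)
    rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      tr <- generate_trial(design$q[i], design$d[i], n_periods)
      rows[[i]] <- data.frame(
        subject_id = s, block = design$block[i], trial = design$trial[i],
        q_level = design$q_level[i], d_level = design$d_level[i],
        q = design$q[i], d = design$d[i],
        period = seq_len(n_periods), signal = tr$signals, regime = tr$regime,
        change_period = tr$change_period
      )
    }
    out[[s]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Quadratic accuracy bonus
#'
#' Payoff (in TWD) for a single probability estimate under the task's
#' quadratic scoring rule: `30 * (0.1 - 0.2 * (P - B)^2)`, where `B` is the
#' regime indicator (1 = blue/shifted, 0 = red). Ranges from -3 to 3 TWD and
#' is maximized exactly when `P == B`.
#'
#' @param P probability estimate in \[0, 1\] (vectorized).
#' @param B regime indicator, 0 or 1 (vectorized).
#' @return numeric vector of payoffs in TWD.
#' @examples
#' bonus(1, 1)    # 3
#' bonus(0, 1)    # -3
#' bonus(0.5, 1)  # 1.5
#' @export
bonus <- function(P, B) {
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1)) {
    stop("probability estimate `P` must lie in [0, 1]", call. = FALSE)
  }
  if (!all(B %in% c(0, 1))) {
    stop("regime indicator `B` must be 0 or 1", call. = FALSE)
  }
  30 * (0.1 - 0.2 * (P - B)^2)
}
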