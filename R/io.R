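#' Fit a cohort from a flat estimates table
#'
#' Convenience pipeline for flat (CSV-style) data: takes a long table with
#' one row per period — columns `subject_id`, `block`, `trial`, `q`, `d`,
#'   `period`, `signal`, `P` (probability estimate; `NA` for timed-out
#' periods) — derives the level indices from the q/d values, fits the
#' requested variant per subject, and summarizes the group-mean parameters.
#'
#' @param data data.frame in the flat format above, or a path to a CSV file
#'   in that format.
#' @param variant model variant to fit.
#' @param ... passed to [fit_subjects()].
#' @return list with `fits` (per-subject `sn_fit`s), `table`
#'   ([fits_to_table()]), and `group_means` (mean alpha and beta per level
#'   across converged subjects).
#' @export
fit_cohort <- function(data, variant = "sn_original", ...) {
  if (is.character(data)) {
    data <- utils::read.csv(data, stringsAsFactors = FALSE)
  }
  need <- c("subject_id", "block", "trial", "q", "d", "period", "signal", "P")
  if (!all(need %in% names(data))) {
    stop("flat table must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  q <- sort(unique(data$q))
  d <- sort(unique(data$d))
  data$q_level <- match(data$q, q)
  data$d_level <- match(data$d, d)
  if (!"missing" %in% names(data)) data$missing <- is.na(data$P)
  fits <- fit_subjects(data, variant = variant, q = q, d = d, ...)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  gm <- list(
    alpha = colMeans(t(vapply(conv, function(f) f$params$alpha[1, ],
                              numeric(3)))),
    beta = colMeans(t(vapply(conv, function(f) f$params$beta[1, ],
                             numeric(3))))
  )
  list(fits = fits, table = fits_to_table(fits), group_means = gm)
}
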