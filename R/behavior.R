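# Per-subject behavioral aggregation: dB conversions, lapse ("nonsensory")
# scores pooled over catch trials, worst-block thresholds, and lapse-adjusted
# ("clean") residual thresholds.

#' dB conversions relative to a task reference
#'
#' `linear_to_db(v, ref) = 20 log10(v / ref)`; `db_to_linear` is the exact
#' inverse. FM depths are expressed in dB re 1 Hz, ITDs in dB re 1 us.
#'
#' @param value linear value(s), > 0.
#' @param db value(s) in dB.
#' @param reference reference in the same linear unit, > 0.
#' @return the converted value(s).
#' @export
linear_to_db <- function(value, reference = 1) {
  stopifnot(all(value > 0), reference > 0)
  20 * log10(value / reference)
}

#' @rdname linear_to_db
#' @export
db_to_linear <- function(db, reference = 1) {
  stopifnot(reference > 0)
  reference * 10^(db / 20)
}

#' Pooled lapse rate from the catch trials of a set of runs
#'
#' Catch-trial errors are pooled over blocks (total incorrect / total catch
#' trials), not averaged as per-block rates, because blocks contribute
#' unequal catch counts.
#'
#' @param runs list of `staircase_run`s for one subject and task.
#' @return list with `lapse_rate`, `n_catch`, `n_catch_incorrect`.
#' @export
compute_lapse_rate <- function(runs) {
  n_catch <- sum(vapply(runs, function(r) r$n_catch, integer(1)))
  n_bad <- sum(vapply(runs, function(r) r$n_catch_incorrect, integer(1)))
  if (n_catch == 0)
    stop("no catch trials: lapse rate undefined for this subject/task")
  list(lapse_rate = n_bad / n_catch, n_catch = n_catch,
       n_catch_incorrect = n_bad)
}

#' Worst (largest) block threshold for one subject/task
#' @param thresholds numeric vector of per-block thresholds (dB).
#' @export
worst_block_threshold <- function(thresholds) {
  stopifnot(length(thresholds) >= 1)
  max(thresholds)
}

#' Summarize a subject's runs for one task
#'
#' Block thresholds are averaged on the dB axis (geometric averaging in
#' linear units), matching how thresholds are reported.
#'
#' @param runs list of `staircase_run`s (blocks).
#' @return list with `threshold_db` (across-block dB mean), `block_thresholds`,
#'   `worst_block_db`, `lapse_rate`, catch counts, `n_flagged`.
#' @export
summarize_task_runs <- function(runs) {
  th <- vapply(runs, function(r) r$threshold, numeric(1))
  lr <- compute_lapse_rate(runs)
  list(threshold_db = mean(th), block_thresholds = th,
       worst_block_db = worst_block_threshold(th),
       lapse_rate = lr$lapse_rate, n_catch = lr$n_catch,
       n_catch_incorrect = lr$n_catch_incorrect,
       n_flagged = sum(vapply(runs, function(r) r$flagged, logical(1))))
}

#' Lapse-adjust thresholds across a cohort
#'
#' Fits ordinary least squares of threshold (dB) on the nonsensory (lapse)
#' score across subjects, separately per task, and returns the residuals as
#' "clean" thresholds together with the fitted line (for measured-vs-
#' predicted plots).
#'
#' @param threshold_db per-subject thresholds (dB).
#' @param lapse_rate per-subject lapse rates in \[0, 1\].
#' @return list with `residuals` (adjusted thresholds), `slope`, `intercept`,
#'   `r_squared`, `fitted`.
#' @export
adjust_thresholds <- function(threshold_db, lapse_rate) {
  stopifnot(length(threshold_db) == length(lapse_rate),
            length(threshold_db) >= 3)
  if (stats::var(lapse_rate) == 0) {
    warning("zero variance in lapse rates: residuals are centered thresholds")
    return(list(residuals = threshold_db - mean(threshold_db),
                slope = 0, intercept = mean(threshold_db),
                r_squared = 0, fitted = rep(mean(threshold_db),
                                            length(threshold_db))))
  }
  fit <- stats::lm(threshold_db ~ lapse_rate)
  list(residuals = unname(stats::residuals(fit)),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       fitted = unname(stats::fitted(fit)))
}
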