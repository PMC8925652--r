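# End-to-end study orchestration on synthetic cohorts: behavior + EEG ->
# per-subject metrics -> cohort table -> adjustment and variance
# partitioning, with parameter-recovery reporting against the latent truth.

#' Behavioral summary for a whole cohort (ITD task, optionally FM)
#'
#' @param cohort ground-truth table from [sample_cohort()].
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param tasks tasks to run (`"itd"` and/or `"fm"`).
#' @return data.frame with per-subject thresholds (dB), worst-block
#'   thresholds, lapse rates and catch counts, one column set per task.
#' @export
cohort_behavior <- function(cohort, config = cohort_config(), seed = 1,
                            tasks = "itd") {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    out <- list(subject = subj$subject)
    for (task in tasks) {
      runs <- render_behavior(subj, task, config, seed)
      s <- summarize_task_runs(runs)
      out[[paste0(task, "_threshold_db")]] <- s$threshold_db
      out[[paste0(task, "_worst_block_db")]] <- s$worst_block_db
      out[[paste0(task, "_lapse_rate")]] <- s$lapse_rate
      out[[paste0(task, "_n_catch")]] <- s$n_catch
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' Cortical metrics for a whole cohort
#'
#' @param cohort ground-truth table from [sample_cohort()].
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param n_trials_per_cond cortical trials per ITD-jump condition.
#' @param conditions jump sizes (us).
#' @param assr also compute the ASSR quality index (slower).
#' @return data.frame with `itc_<cond>` scalars, `latency_ms`, `slope` and
#'   optionally `assr_itc` per subject.
#' @export
cohort_cortical <- function(cohort, config = cohort_config(), seed = 1,
                            n_trials_per_cond = 300,
                            conditions = c(20, 60, 180, 540), assr = FALSE) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    ep <- render_cortical_eeg(subj, conditions, n_trials_per_cond, seed,
                              config)
    m <- cortical_condition_metrics(ep, assr = assr)
    out <- c(list(subject = subj$subject),
             stats::setNames(as.list(m$itc_scalars),
                             paste0("itc_", names(m$itc_scalars))),
             list(latency_ms = 1000 * m$latency_s, slope = m$slope))
    if (assr) out$assr_itc <- m$assr$itc
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' FFR metrics for a whole cohort
#'
#' @param cohort ground-truth table from [sample_cohort()].
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param n_trials FFR trials per subject.
#' @return data.frame with `d1`, `d2`, `s1`, `s2`, `r_d`, `r_s`, ratios.
#' @export
cohort_ffr <- function(cohort, config = cohort_config(), seed = 1,
                       n_trials = 8000) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    ep <- render_ffr(subj, n_trials, seed, config)
    m <- ffr_metrics(ep, seed = derive_seed(seed, subj$subject, 11))
    data.frame(subject = subj$subject, d1 = m$d1, d2 = m$d2, s1 = m$s1,
               s2 = m$s2, r_d = m$r_d, r_s = m$r_s,
               ratio_d = m$ratio_d, ratio_s = m$ratio_s)
  })
  do.call(rbind, rows)
}

#' Run one full synthetic study (behavior + cortical EEG, optional FFR)
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param n_trials_per_cond cortical trials per condition.
#' @param tasks behavioral tasks.
#' @param ffr include FFR rendering and metrics.
#' @return list with `cohort` (measured table incl. lapse-adjusted ITD
#'   thresholds), `ground_truth`, and the per-task `adjustment` fits.
#' @export
simulate_cohort_study <- function(config = cohort_config(), seed = 1,
                                  n_trials_per_cond = 300, tasks = "itd",
                                  ffr = FALSE) {
  truth <- sample_cohort(config, seed)
  beh <- cohort_behavior(truth, config, seed, tasks)
  cort <- cohort_cortical(truth, config, seed, n_trials_per_cond)
  tab <- merge(beh, cort, by = "subject")
  adjustment <- list()
  for (task in tasks) {
    adj <- adjust_thresholds(tab[[paste0(task, "_threshold_db")]],
                             tab[[paste0(task, "_lapse_rate")]])
    tab[[paste0(task, "_threshold_adj_db")]] <- adj$residuals
    adjustment[[task]] <- adj
  }
  if (ffr) tab <- merge(tab, cohort_ffr(truth, config, seed), by = "subject")
  list(cohort = tab, ground_truth = truth, adjustment = adjustment)
}

#' End-to-end parameter-recovery report
#'
#' The acceptance surface standing in for human-data correlations (which
#' need the original cohort): across `n_cohorts` synthetic cohorts,
#' lapse-adjusted ITD thresholds should track the true binaural sensory
#' parameter theta_b more closely than raw thresholds; on the EEG cohort the
#' latency and slope metrics should correlate with theta_b, the raw ITC
#' scalar should be confounded by the anatomy gain, and the hierarchical
#' regression report should partition threshold variance over nonsensory
#' score, EEG latency and EEG slope.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param n_cohorts number of behavioral cohorts simulated.
#' @param n_eeg_trials_per_cond cortical trials per condition for the EEG
#'   cohort (the first cohort).
#' @param eeg run the EEG forward model on the first cohort.
#' @return list with `frac_adjusted_better`, per-cohort raw/adjusted
#'   correlations, EEG-cohort correlations (`latency`, `slope`, `itc_gain`,
#'   `itc_theta`), latency recovery error, and the `regression` report.
#' @export
end_to_end_recovery <- function(config = cohort_config(), seed = 1,
                                n_cohorts = 100, n_eeg_trials_per_cond = 100,
                                eeg = TRUE) {
  r_raw <- r_adj <- numeric(n_cohorts)
  first <- NULL
  for (k in seq_len(n_cohorts)) {
    cseed <- derive_seed(seed, k)
    truth <- sample_cohort(config, cseed)
    beh <- cohort_behavior(truth, config, cseed, tasks = "itd")
    adj <- adjust_thresholds(beh$itd_threshold_db, beh$itd_lapse_rate)
    r_raw[k] <- pearson_r(beh$itd_threshold_db, truth$theta_b)$r
    r_adj[k] <- pearson_r(adj$residuals, truth$theta_b)$r
    if (k == 1) first <- list(truth = truth, beh = beh, adj = adj)
  }
  out <- list(frac_adjusted_better = mean(r_adj > r_raw),
              r_raw = r_raw, r_adj = r_adj,
              mean_r_raw = mean(r_raw), mean_r_adj = mean(r_adj))
  if (eeg) {
    cseed <- derive_seed(seed, 1)
    cort <- cohort_cortical(first$truth, config, cseed,
                            n_trials_per_cond = n_eeg_trials_per_cond)
    truth <- first$truth
    out$eeg <- list(
      r_latency_theta = pearson_r(cort$latency_ms, truth$theta_b)$r,
      r_slope_theta = pearson_r(cort$slope, truth$theta_b)$r,
      r_itc540_gain = pearson_r(cort$itc_540, truth$eeg_gain)$r,
      r_itc540_theta = pearson_r(cort$itc_540, truth$theta_b)$r,
      latency_mae_ms = mean(abs(cort$latency_ms -
                                  1000 * (0.15 + truth$eeg_latency_shift))))
    out$regression <- stepwise_incremental_r2(
      first$beh$itd_threshold_db,
      list(nonsensory = first$beh$itd_lapse_rate,
           eeg_latency = cort$latency_ms,
           eeg_slope = cort$slope))
  }
  out
}

#' Run a full synthetic study and write its outputs to a directory
#'
#' Writes `cohort.csv`, `ground_truth.csv`, `report.json` (adjustment fits
#' and the regression partition) and `config.json` (the exact configuration
#' and seed needed to regenerate everything).
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param ... passed to [simulate_cohort_study()].
#' @return the study list, invisibly.
#' @export
run_study <- function(config = cohort_config(), out_dir, seed = 1, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  study <- simulate_cohort_study(config, seed, ...)
  write_cohort_csv(study$cohort, file.path(out_dir, "cohort.csv"))
  write_cohort_csv(study$ground_truth, file.path(out_dir, "ground_truth.csv"))
  reg <- stepwise_incremental_r2(
    study$cohort$itd_threshold_db,
    list(nonsensory = study$cohort$itd_lapse_rate,
         eeg_latency = study$cohort$latency_ms,
         eeg_slope = study$cohort$slope))
  jsonlite::write_json(
    list(adjustment = study$adjustment,
         regression = list(predictors = reg$predictors,
                           incremental_r2_pct = as.list(reg$incremental_r2_pct),
                           explained_pct = reg$explained_pct,
                           unexplained_pct = reg$unexplained_pct)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(unclass(config), list(seed = seed)),
                       file.path(out_dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(study)
}
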