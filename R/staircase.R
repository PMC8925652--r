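# Adaptive staircase psychophysics with a lapse-capable simulated observer.
#
# The observer separates sensory coding (midpoint/spread of a logistic
# psychometric function on the dB-transformed stimulus axis) from nonsensory
# behavior (lapse rate lambda): on a lapse the response is at chance,
# regardless of stimulus strength, so the asymptote is 1 - lambda... more
# precisely guess + (1 - guess - lambda) at +Inf.

#' A simulated 2AFC observer with independent sensory and lapse parameters
#'
#' `P(correct | x) = guess + (1 - guess - lapse) * F((x - midpoint)/spread)`
#' with `F` the standard logistic. `x` is on the task's dB axis (dB re 1 Hz
#' for FM depth, dB re 1 us for ITD).
#'
#' @param midpoint stimulus value (dB) at which the sensory term reaches
#'   half range.
#' @param spread logistic scale in dB (> 0).
#' @param lapse lapse probability in \[0, 0.5).
#' @param guess guess rate (0.5 for 2AFC).
#' @return an object of class `psychometric_observer`.
#' @export
psychometric_observer <- function(midpoint, spread, lapse = 0, guess = 0.5) {
  stopifnot(spread > 0, lapse >= 0, lapse < 0.5, guess >= 0, guess < 1)
  structure(list(midpoint = midpoint, spread = spread, lapse = lapse,
                 guess = guess),
            class = "psychometric_observer")
}

#' Probability of a correct response at stimulus value x
#' @param observer a [psychometric_observer()].
#' @param x stimulus value(s) on the dB axis.
#' @export
observer_p_correct <- function(observer, x) {
  observer$guess + (1 - observer$guess - observer$lapse) *
    stats::plogis((x - observer$midpoint) / observer$spread)
}

#' Draw Bernoulli responses from the observer
#'
#' Uses the current RNG stream; seed at the run level (see
#' [run_staircase()]) for reproducibility.
#'
#' @param observer a [psychometric_observer()].
#' @param x stimulus value(s), finite.
#' @return logical vector of correct/incorrect.
#' @export
observer_respond <- function(observer, x) {
  stopifnot(all(is.finite(x)))
  stats::runif(length(x)) < observer_p_correct(observer, x)
}

#' Invert the psychometric function at a target proportion correct
#' @param observer a [psychometric_observer()].
#' @param p target proportion correct (must be attainable).
#' @return the stimulus value (dB) where `P(correct) = p`.
#' @export
observer_quantile <- function(observer, p) {
  f <- (p - observer$guess) / (1 - observer$guess - observer$lapse)
  if (f <= 0 || f >= 1) stop("target proportion not attainable")
  observer$midpoint + observer$spread * stats::qlogis(f)
}

#' Asymptotic percent-correct target of a staircase rule
#'
#' `3down1up` converges to the p with p^3 = 1/2 (79.37% correct); the
#' weighted 3:1 one-down-one-up rule converges to the equilibrium of
#' `p * s_down = (1 - p) * s_up`, i.e. 75% for an up step three times the
#' down step.
#'
#' @param rule `"3down1up"` or `"weighted_1down1up_3to1"`.
#' @return target proportion correct.
#' @export
staircase_target_p <- function(rule = c("3down1up", "weighted_1down1up_3to1")) {
  rule <- match.arg(rule)
  switch(rule,
         "3down1up" = 0.5^(1 / 3),
         "weighted_1down1up_3to1" = 3 / 4)
}

#' Configuration of an adaptive track
#'
#' @param rule adaptation rule: `"weighted_1down1up_3to1"` (up step = 3 x
#'   down step) or `"3down1up"`.
#' @param start starting stimulus value (dB).
#' @param step_initial,step_final down-step sizes in dB; the step shrinks
#'   from initial to final after `shrink_after_reversals` reversals.
#' @param shrink_after_reversals reversal count at which the step shrinks.
#' @param n_reversals_stop stop after this many reversals.
#' @param threshold_rule `"median_all_reversals"` or `"geomean_last9"`
#'   (geometric mean in linear units = arithmetic mean of the last nine
#'   reversal values on the dB axis).
#' @param catch_bound_db catch-trial criterion: trials with presented value
#'   strictly above this dB bound count as easy "catch" trials.
#' @param floor,ceiling presentation clamps on the dB axis.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(rule = c("weighted_1down1up_3to1", "3down1up"),
                             start, step_initial = 4, step_final = 2,
                             shrink_after_reversals = 3, n_reversals_stop = 11,
                             threshold_rule = c("median_all_reversals",
                                                "geomean_last9"),
                             catch_bound_db = Inf,
                             floor = -20, ceiling = 60) {
  rule <- match.arg(rule)
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(step_initial > 0, step_final > 0, n_reversals_stop >= 2,
            floor < ceiling)
  if (threshold_rule == "geomean_last9" && n_reversals_stop < 9)
    stop("geomean_last9 needs at least 9 reversals")
  structure(list(rule = rule, start = start, step_initial = step_initial,
                 step_final = step_final,
                 shrink_after_reversals = shrink_after_reversals,
                 n_reversals_stop = n_reversals_stop,
                 threshold_rule = threshold_rule,
                 catch_bound_db = catch_bound_db,
                 floor = floor, ceiling = ceiling),
            class = "staircase_config")
}

#' Preset track for the FM-detection task (dB re 1 Hz)
#'
#' Weighted (3:1) one-down-one-up, stopped after 11 reversals, threshold =
#' median of all reversals; catch trials are depths above 15 Hz. The track
#' starts above the catch bound so every block contains easy trials.
#' @param ... overrides passed to [staircase_config()].
#' @export
fm_staircase_config <- function(...) {
  defaults <- list(rule = "weighted_1down1up_3to1", start = 28,
                   step_initial = 4, step_final = 2,
                   shrink_after_reversals = 3, n_reversals_stop = 11,
                   threshold_rule = "median_all_reversals",
                   catch_bound_db = 20 * log10(15),   # >15 Hz re 1 Hz
                   floor = -10, ceiling = 40)
  do.call(staircase_config, utils::modifyList(defaults, list(...)))
}

#' Preset track for the ITD-detection task (dB re 1 us)
#'
#' Three-down-one-up, threshold = geometric mean of the last nine reversals
#' (12 reversals per block); catch trials are ITDs above 80 us.
#' @param ... overrides passed to [staircase_config()].
#' @export
itd_staircase_config <- function(...) {
  defaults <- list(rule = "3down1up", start = 44,
                   step_initial = 4, step_final = 2,
                   shrink_after_reversals = 3, n_reversals_stop = 12,
                   threshold_rule = "geomean_last9",
                   catch_bound_db = 20 * log10(80),   # >80 us re 1 us
                   floor = 0, ceiling = 56)
  do.call(staircase_config, utils::modifyList(defaults, list(...)))
}

#' Run one adaptive track against an observer
#'
#' @param observer a [psychometric_observer()].
#' @param config a [staircase_config()].
#' @param seed RNG seed for the run (NULL = current stream).
#' @param max_trials hard safety cap.
#' @return an object of class `staircase_run`: trial log (`trials`:
#'   data.frame with value, correct, is_catch), reversal values (dB),
#'   `threshold` (dB), catch counts, and a `flagged` indicator set when the
#'   track sat clamped at the floor/ceiling more than three consecutive
#'   times.
#' @export
run_staircase <- function(observer, config, seed = NULL, max_trials = 2000) {
  local_seed(seed, {
    value <- config$start
    n_down_needed <- if (config$rule == "3down1up") 3L else 1L
    up_factor <- if (config$rule == "weighted_1down1up_3to1") 3 else 1
    values <- numeric(0); corrects <- logical(0)
    reversals <- numeric(0)
    last_dir <- 0L          # -1 down, +1 up
    n_correct_streak <- 0L
    clamp_streak <- 0L; flagged <- FALSE
    while (length(reversals) < config$n_reversals_stop &&
           length(values) < max_trials) {
      presented <- min(max(value, config$floor), config$ceiling)
      clamped <- presented != value
      clamp_streak <- if (clamped) clamp_streak + 1L else 0L
      if (clamp_streak > 3L) flagged <- TRUE
      correct <- observer_respond(observer, presented)
      values <- c(values, presented); corrects <- c(corrects, correct)
      step <- if (length(reversals) >= config$shrink_after_reversals)
        config$step_final else config$step_initial
      move <- 0L
      if (correct) {
        n_correct_streak <- n_correct_streak + 1L
        if (n_correct_streak >= n_down_needed) {
          move <- -1L; n_correct_streak <- 0L
        }
      } else {
        n_correct_streak <- 0L
        move <- +1L
      }
      if (move != 0L) {
        if (last_dir != 0L && move != last_dir)
          reversals <- c(reversals, presented)
        last_dir <- move
        value <- presented + ifelse(move < 0, -step, up_factor * step)
      }
    }
    threshold <- staircase_threshold(reversals, config$threshold_rule)
    run <- structure(list(
      trials = data.frame(trial = seq_along(values), value = values,
                          correct = corrects, is_catch = NA),
      reversals = reversals, threshold = threshold,
      config = config, n_catch = NA_integer_,
      n_catch_incorrect = NA_integer_, flagged = flagged),
      class = "staircase_run")
    flag_catch_trials(run)
  })
}

# threshold from reversal values per rule (dB axis)
staircase_threshold <- function(reversals, rule) {
  if (length(reversals) == 0) return(NA_real_)
  switch(rule,
         median_all_reversals = stats::median(reversals),
         geomean_last9 = mean(utils::tail(reversals, 9)))
}

#' Flag catch trials and update the lapse-relevant counts of a run
#'
#' A trial is a catch trial when its presented stimulus value exceeds the
#' configured bound (strictly: a trial exactly at the bound is not easy
#' enough to count).
#'
#' @param run a `staircase_run`.
#' @param catch_bound_db override for the config's bound (dB).
#' @return the run with `is_catch`, `n_catch`, `n_catch_incorrect` updated.
#' @export
flag_catch_trials <- function(run, catch_bound_db = NULL) {
  bound <- if (is.null(catch_bound_db)) run$config$catch_bound_db else catch_bound_db
  is_catch <- run$trials$value > bound + 1e-9
  run$trials$is_catch <- is_catch
  run$n_catch <- sum(is_catch)
  run$n_catch_incorrect <- sum(is_catch & !run$trials$correct)
  run
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("<staircase_run> %s: %d trials, %d reversals, threshold %.2f dB, %d/%d catch errors%s\n",
              x$config$rule, nrow(x$trials), length(x$reversals),
              x$threshold, x$n_catch_incorrect, x$n_catch,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Export a set of runs as a TSV trial log
#' @param runs list of `staircase_run`s (one per block).
#' @param path output path.
#' @param unit axis unit string stored per trial (e.g. "dB re 1 us").
#' @export
write_trial_log <- function(runs, path, unit = "dB") {
  tab <- do.call(rbind, lapply(seq_along(runs), function(b) {
    tr <- runs[[b]]$trials
    data.frame(block = b, trial = tr$trial, stimulus_value = tr$value,
               unit = unit, correct = tr$correct, is_catch = tr$is_catch)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
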