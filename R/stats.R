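# Correlation, hierarchical (fixed-entry-order) incremental variance
# partitioning, and false-discovery-rate control.

#' Pearson correlation with a two-sided p value
#'
#' Pairwise-complete observations; p from the exact t transform
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Incremental R-squared partition with fixed predictor entry order
#'
#' Predictors are entered one by one in the given order (hierarchical
#' regression with sequential, Type-I, variance attribution): the increment
#' of step k is `R2(first k) - R2(first k-1)`, reported in percent. The
#' increments sum exactly to the full-model R2, so explained + unexplained
#' = 100%.
#'
#' @param y response vector.
#' @param predictors named list (or data.frame) of predictor vectors, in
#'   entry order.
#' @return an object of class `regression_report`: `predictors` (entry
#'   order), `incremental_r2_pct`, `explained_pct`, `unexplained_pct`,
#'   `coefficients` (full model), `fitted`, `residuals`, `collinear`
#'   (flags increments that are numerically zero).
#' @export
stepwise_incremental_r2 <- function(y, predictors) {
  predictors <- as.data.frame(predictors)
  k <- ncol(predictors)
  stopifnot(k >= 1, length(y) > k + 1)
  r2 <- numeric(k)
  fit <- NULL
  for (i in seq_len(k)) {
    dat <- cbind(y = y, predictors[, seq_len(i), drop = FALSE])
    fit <- stats::lm(y ~ ., data = dat)
    r2[i] <- summary(fit)$r.squared
  }
  inc <- diff(c(0, r2)) * 100
  structure(list(predictors = names(predictors),
                 incremental_r2_pct = stats::setNames(inc, names(predictors)),
                 explained_pct = r2[k] * 100,
                 unexplained_pct = (1 - r2[k]) * 100,
                 coefficients = stats::coef(fit),
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 collinear = abs(inc) < 1e-10),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("Predictor\tVariance explained\n")
  for (i in seq_along(x$predictors))
    cat(sprintf("%s\t%.2f%%\n", x$predictors[i], x$incremental_r2_pct[i]))
  cat(sprintf("Explained\t%.2f%%\nUnexplained\t%.2f%%\n",
              x$explained_pct, x$unexplained_pct))
  invisible(x)
}

#' Format a regression report as a Markdown table
#' @param report a `regression_report`.
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  c("| Predictor | Variance explained |",
    "| --- | --- |",
    sprintf("| %s | %.2f%% |", report$predictors,
            report$incremental_r2_pct),
    sprintf("| Explained | %.2f%% |", report$explained_pct),
    sprintf("| Unexplained | %.2f%% |", report$unexplained_pct))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up rule: reject all hypotheses with `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param p_values p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical rejection flags, in the input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value set")
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}
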