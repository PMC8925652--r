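# Independent oracles and small fixture builders used across the suite.

# band-limited sinc interpolation by factor k via FFT zero-padding
fft_upsample <- function(x, k) {
  n <- length(x)
  X <- stats::fft(x)
  m <- n * k
  Y <- rep(0 + 0i, m)
  half <- floor(n / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 1) Y[m - (1:(half - 1)) + 1] <- X[n - (1:(half - 1)) + 1]
  Re(stats::fft(Y, inverse = TRUE)) * k / n
}

# interaural lag by brute-force cross-correlation on a 10x upsampled grid;
# positive lag = left channel leads (right is delayed). Independent of the
# synthesis path (no shared code with frac_delay).
xcorr_lag_us <- function(left, right, fs, upsample = 10, max_lag_us = 800) {
  lu <- fft_upsample(left, upsample)
  ru <- fft_upsample(right, upsample)
  fsu <- fs * upsample
  max_lag <- round(max_lag_us * 1e-6 * fsu)
  lags <- -max_lag:max_lag
  n <- length(lu)
  cc <- vapply(lags, function(d) {
    if (d >= 0) sum(lu[1:(n - d)] * ru[(1 + d):n])
    else sum(lu[(1 - d):n] * ru[1:(n + d)])
  }, numeric(1))
  lags[which.max(cc)] / fsu * 1e6
}

# Hilbert envelope / instantaneous frequency via the analytic signal (FFT)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hilbert_envelope <- function(x) Mod(analytic_signal(x))

inst_freq_hz <- function(x, fs) {
  ph <- Arg(analytic_signal(x))
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi
  dph * fs / (2 * pi)
}

# amplitude spectrum (one-sided) of a signal
amp_spectrum <- function(x, fs) {
  n <- length(x)
  a <- 2 * Mod(stats::fft(x)) / n
  f <- (0:(n - 1)) * fs / n
  keep <- 1:floor(n / 2)
  list(f = f[keep], a = a[keep])
}

# brute-force BH step-up over all candidate thresholds
bh_brute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= (seq_len(m)) * q / m)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[1:max(ks)]] <- TRUE
  rej
}

# single-channel epoch array from a trials x time matrix
make_epochs <- function(x, rate, tmin, labels = NULL) {
  epoch_array(array(x, c(nrow(x), 1, ncol(x))), rate, tmin,
              channels = "Cz", labels = labels)
}

# a latent subject row with explicit fields (defaults: median subject)
make_subject <- function(theta_b = 29, theta_m = 14, lapse = 0, gain = 1,
                         tau = 0, mid_log = log(60), steep = 0.45,
                         An = 0.1, Ac = 0.2, alpha = 0.8, id = 1) {
  data.frame(subject = id, theta_b = theta_b, theta_m = theta_m,
             lapse = lapse, eeg_gain = gain, eeg_latency_shift = tau,
             itd_mid_log = mid_log, itd_steep = steep,
             ffr_A_neural = An, ffr_A_preneural = Ac, ffr_alpha = alpha)
}

# staircase run skeleton for metric-level tests
make_run <- function(values, correct, config) {
  structure(list(trials = data.frame(trial = seq_along(values),
                                     value = values, correct = correct,
                                     is_catch = NA),
                 reversals = numeric(0), threshold = NA_real_,
                 config = config, n_catch = NA_integer_,
                 n_catch_incorrect = NA_integer_, flagged = FALSE),
            class = "staircase_run")
}
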