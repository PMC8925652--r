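# Cortical ITD-jump metrics: intertrial coherence (ITC) spectrograms from a
# complex Morlet decomposition, the low-band (1-20 Hz) ITC time course and
# per-condition jump scalar, 40.8-Hz ASSR quality, N1/P2 latency, and the
# normalized ITD-growth slope.

# complex Morlet time-frequency transform of a trials x time matrix
# returns trials x n_freqs x time complex array
morlet_tfr <- function(x, rate, freqs, n_cycles = pmin(5, pmax(3, freqs))) {
  stopifnot(is.matrix(x))
  n_trials <- nrow(x); nt <- ncol(x)
  n_cycles <- rep(n_cycles, length.out = length(freqs))
  # choose one fft length covering the longest wavelet
  half_max <- max(vapply(seq_along(freqs), function(i) {
    sigma_t <- n_cycles[i] / (2 * pi * freqs[i])
    min(floor(3.5 * sigma_t * rate), floor((nt - 1) / 2))
  }, numeric(1)))
  lw_max <- 2 * half_max + 1
  nfft <- stats::nextn(nt + lw_max - 1, 2)
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - nt, n_trials)))
  out <- array(0i, c(n_trials, length(freqs), nt))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma_t <- n_cycles[i] / (2 * pi * f)
    half <- min(floor(3.5 * sigma_t * rate), floor((nt - 1) / 2))
    tw <- (-half:half) / rate
    w <- exp(-tw^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tw)
    w <- w / sum(abs(w))
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::mvfft(X * W, inverse = TRUE) / nfft
    out[, i, ] <- t(conv[half + (1:nt), , drop = FALSE])
  }
  out
}

#' Intertrial coherence map from an epoch tensor
#'
#' For each time-frequency point, trials' complex Morlet coefficients are
#' reduced to unit phasors and averaged; the ITC is the modulus of that mean
#' (0 = no phase locking, 1 = perfect phase consistency). ITC is a
#' phase-only statistic: it is exactly invariant to global amplitude scaling
#' of the epoch tensor.
#'
#' @param epochs an [epoch_array()].
#' @param channel channel used (default `"Cz"`).
#' @param freqs frequency grid in Hz (default 1-50 Hz at 1-Hz spacing).
#' @param n_cycles wavelet width in cycles per frequency (default 5, floored
#'   at 3 for the lowest frequencies).
#' @return an object of class `itc_map`: `values` (freqs x times in \[0,1\]),
#'   `freqs`, `times`, `n_trials`.
#' @export
compute_itc <- function(epochs, channel = "Cz", freqs = 1:50,
                        n_cycles = pmin(5, pmax(3, freqs))) {
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stop("channel '", channel, "' not found")
  trials <- good_trials(epochs)
  if (length(trials) < 2) stop("ITC needs at least 2 surviving trials")
  x <- matrix(epochs$data[trials, ci, ], nrow = length(trials))
  tfr <- morlet_tfr(x, epochs$rate, freqs, n_cycles)
  mod <- Mod(tfr)
  mod[mod == 0] <- 1
  values <- Mod(colMeans(tfr / mod))   # mean over trials (dim 1)
  structure(list(values = values, freqs = freqs, times = epochs$times,
                 n_trials = length(trials)),
            class = "itc_map")
}

#' Low-band ITC time course and jump-evoked condition scalar
#'
#' Averages the ITC map over `[fmin, fmax]` Hz (default 1-20 Hz, below the
#' 40.8-Hz ASSR) to one time course; the condition scalar is the peak of
#' that time course in the post-jump window minus the mean over the
#' pre-jump baseline, which supplies the noise floor.
#'
#' @param itcmap an `itc_map` from [compute_itc()].
#' @param fmin,fmax band edges (Hz).
#' @param peak_window post-event window searched for the peak (s).
#' @param baseline_window pre-event window averaged as baseline (s).
#' @return list with `timecourse`, `times`, `scalar`, `baseline`, `peak`.
#' @export
lowband_itc_timecourse <- function(itcmap, fmin = 1, fmax = 20,
                                   peak_window = c(0, 0.4),
                                   baseline_window = c(-0.4, 0)) {
  sel <- itcmap$freqs >= fmin & itcmap$freqs <= fmax
  if (max(itcmap$freqs) < fmax)
    stop("frequency grid does not reach ", fmax, " Hz")
  ts <- colMeans(itcmap$values[sel, , drop = FALSE])
  tt <- itcmap$times
  post <- tt > peak_window[1] & tt <= peak_window[2]
  pre <- tt > baseline_window[1] & tt <= baseline_window[2]
  stopifnot(any(post), any(pre))
  peak <- max(ts[post]); base <- mean(ts[pre])
  list(timecourse = ts, times = tt, scalar = peak - base,
       baseline = base, peak = peak)
}

#' ASSR recording-quality index: ITC at the modulation frequency
#'
#' The 40.8-Hz steady-state response should be phase locked across trials
#' whenever the recording is usable; its ITC over the stimulus-on interval
#' is compared against phase-randomized surrogates (each trial's phase
#' rotated by an independent uniform angle, preserving within-trial
#' structure) to obtain a noise floor.
#'
#' @param epochs an [epoch_array()].
#' @param channel channel used.
#' @param freq_hz modulation frequency (default 40.8).
#' @param stim_window interval (s, relative to the alignment event) over
#'   which the ITC is averaged; defaults to the pre-event half of the epoch,
#'   where the steady-state drive is on in the jump paradigm.
#' @param n_cycles wavelet width (default 16: the steady-state response is
#'   narrowband, and a long wavelet keeps nearby transient energy out).
#' @param n_surrogates number of phase-randomized surrogates.
#' @param seed surrogate RNG seed.
#' @return list with `itc`, `noise_floor` (99th surrogate percentile),
#'   `above_floor` flag.
#' @export
assr_quality <- function(epochs, channel = "Cz", freq_hz = 40.8,
                         stim_window = NULL, n_cycles = 16,
                         n_surrogates = 200, seed = 1) {
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stop("channel '", channel, "' not found")
  trials <- good_trials(epochs)
  if (length(trials) < 2) stop("ITC needs at least 2 surviving trials")
  if (is.null(stim_window)) stim_window <- c(epochs$times[1], 0)
  x <- matrix(epochs$data[trials, ci, ], nrow = length(trials))
  tfr <- morlet_tfr(x, epochs$rate, freq_hz, n_cycles)
  sel <- epochs$times >= stim_window[1] & epochs$times <= stim_window[2]
  ph <- tfr[, 1, sel, drop = FALSE][, 1, ]
  ph <- matrix(ph, nrow = length(trials))
  modz <- Mod(ph); modz[modz == 0] <- 1
  phasors <- ph / modz
  itc <- mean(Mod(colMeans(phasors)))
  surr <- local_seed(seed, vapply(seq_len(n_surrogates), function(s) {
    rot <- exp(2i * pi * stats::runif(nrow(phasors)))
    mean(Mod(colMeans(phasors * rot)))
  }, numeric(1)))
  floor99 <- stats::quantile(surr, 0.99, names = FALSE)
  list(itc = itc, noise_floor = floor99, above_floor = itc > floor99)
}

#' Detect N1 and P2 peaks of the jump-evoked response
#'
#' N1 is the most negative extremum in its post-event window and P2 the most
#' positive in its (later) window; P2 is constrained to follow N1. The
#' latency metric is the mean of the two latencies, both relative to the
#' alignment (jump) event at t = 0.
#'
#' @param evoked averaged evoked trace (uV) over `times`.
#' @param times time axis (s) relative to the jump.
#' @param n1_window,p2_window search windows (s) after the jump.
#' @return an object of class `evoked_peaks`: `n1_latency`, `n1_amplitude`,
#'   `p2_latency`, `p2_amplitude`, `latency_metric`.
#' @export
detect_n1_p2 <- function(evoked, times, n1_window = c(0.05, 0.20),
                         p2_window = c(0.15, 0.35)) {
  stopifnot(length(evoked) == length(times))
  in_n1 <- times > n1_window[1] & times <= n1_window[2]
  if (!any(in_n1)) stop("N1 window empty")
  i_n1 <- which(in_n1)[which.min(evoked[in_n1])]
  n1_lat <- times[i_n1]
  in_p2 <- times > max(p2_window[1], n1_lat) & times <= p2_window[2]
  if (!any(in_p2)) stop("no P2 candidate after N1: peaks undefined")
  i_p2 <- which(in_p2)[which.max(evoked[in_p2])]
  p2_lat <- times[i_p2]
  structure(list(n1_latency = n1_lat, n1_amplitude = evoked[i_n1],
                 p2_latency = p2_lat, p2_amplitude = evoked[i_p2],
                 latency_metric = mean(c(n1_lat, p2_lat))),
            class = "evoked_peaks")
}

#' Normalized ITD-growth slope
#'
#' `(ITC_180 - ITC_60) / ITC_540`: the rise of the jump-evoked response
#' between the 60- and 180-us conditions, normalized by the (near-saturated)
#' 540-us response so that any global amplitude scale (e.g. anatomy)
#' cancels.
#'
#' @param scalars named numeric vector with elements `"60"`, `"180"`,
#'   `"540"` (condition ITC scalars).
#' @param noise_floor the slope is undefined (NA) when the 540-us scalar is
#'   at or below this floor.
#' @return the slope (dimensionless) or NA.
#' @export
itd_growth_slope <- function(scalars, noise_floor = 0) {
  need <- c("60", "180", "540")
  stopifnot(all(need %in% names(scalars)))
  if (scalars[["540"]] <= noise_floor) return(NA_real_)
  (scalars[["180"]] - scalars[["60"]]) / scalars[["540"]]
}

#' Per-condition cortical metrics for one subject
#'
#' Splits the epoch tensor by ITD-jump condition label, computes the
#' low-band ITC scalar per condition, N1/P2 latency on the reference
#' condition (180 us, chosen to avoid floor and ceiling effects), the ASSR
#' quality index, and the normalized growth slope.
#'
#' @param epochs an [epoch_array()] whose `labels` carry the jump size in us.
#' @param channel channel used.
#' @param freqs ITC frequency grid.
#' @param latency_condition condition used for the latency metric.
#' @param assr if TRUE also compute the ASSR quality index.
#' @return list with `itc_scalars` (named by condition), `peaks`,
#'   `latency_s`, `slope`, and optionally `assr`.
#' @export
cortical_condition_metrics <- function(epochs, channel = "Cz", freqs = 1:20,
                                       latency_condition = "180",
                                       assr = FALSE) {
  stopifnot(!is.null(epochs$labels))
  conds <- sort(unique(as.numeric(epochs$labels)))
  scalars <- vapply(conds, function(cc) {
    sub <- subset_epochs(epochs, which(as.numeric(epochs$labels) == cc))
    m <- compute_itc(sub, channel, freqs)
    lowband_itc_timecourse(m)$scalar
  }, numeric(1))
  names(scalars) <- as.character(conds)
  sub <- subset_epochs(epochs,
                       which(as.character(epochs$labels) == latency_condition))
  ev <- evoked_average(sub, channel)
  peaks <- detect_n1_p2(ev, sub$times)
  slope <- if (all(c("60", "180", "540") %in% names(scalars)))
    itd_growth_slope(scalars) else NA_real_
  out <- list(itc_scalars = scalars, peaks = peaks,
              latency_s = peaks$latency_metric,
              slope = slope)
  if (assr) out$assr <- assr_quality(epochs, channel)
  out
}

#' Subset an epoch array by trial indices
#' @param epochs an [epoch_array()].
#' @param trials trial indices to keep.
#' @export
subset_epochs <- function(epochs, trials) {
  epoch_array(epochs$data[trials, , , drop = FALSE], epochs$rate,
              epochs$tmin, epochs$channels,
              labels = if (is.null(epochs$labels)) NULL else epochs$labels[trials],
              rejected = epochs$rejected[trials],
              alignment = epochs$alignment)
}
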