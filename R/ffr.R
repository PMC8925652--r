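# Forward-masked FFR decomposition.
#
# Alternating-polarity epochs are split into the difference average (tracks
# the 500-Hz temporal fine structure: neural + preneural/CM components) and
# the sum average (envelope-related; carries the 1000-Hz rectification
# component). Subtracting the probe-2 segment from the probe-1 segment
# cancels the masking-insensitive preneural part and leaves the adaptable
# neural residual.

#' Split alternating-polarity FFR epochs into difference and sum averages
#'
#' `diff = (mean(+) - mean(-))/2`, `sum = (mean(+) + mean(-))/2`, computed
#' over surviving trials after balancing the two polarity classes by seeded
#' random subsampling of the larger class (unequal counts would leak
#' envelope components into the difference).
#'
#' @param epochs an [epoch_array()] whose `labels` are +1 / -1 polarities.
#' @param seed subsampling seed.
#' @return list with `diff`, `sum` (uV time series over `times`), `times`,
#'   `rate`, `n_per_polarity`.
#' @export
polarity_decompose <- function(epochs, seed = 1) {
  stopifnot(!is.null(epochs$labels))
  pol <- as.numeric(epochs$labels)
  good <- good_trials(epochs)
  pos <- intersect(which(pol == 1), good)
  neg <- intersect(which(pol == -1), good)
  if (!length(pos) || !length(neg))
    stop("both polarities must be present after rejection")
  n <- min(length(pos), length(neg))
  local_seed(seed, {
    if (length(pos) > n) pos <- sample(pos, n)
    if (length(neg) > n) neg <- sample(neg, n)
  })
  ci <- 1L  # FFR container carries the single analysis channel
  mp <- colMeans(matrix(epochs$data[pos, ci, ], nrow = length(pos)))
  mn <- colMeans(matrix(epochs$data[neg, ci, ], nrow = length(neg)))
  list(diff = (mp - mn) / 2, sum = (mp + mn) / 2,
       times = epochs$times, rate = epochs$rate, n_per_polarity = n)
}

#' Spectral magnitude of an average at a target frequency, with noise floor
#'
#' Hann-tapered discrete spectrum of the windowed segment; the component
#' magnitude is read at the bin nearest `target_hz` (scaled so an on-bin
#' sinusoid of amplitude A reports A), and the noise floor is the mean
#' magnitude over the `n_neighbors` bins on each side excluding the 2 bins
#' adjacent to the target.
#'
#' @param avg time series (uV) over `times`.
#' @param times time axis (s).
#' @param rate sampling rate.
#' @param window segment window (s, two values) analyzed.
#' @param target_hz target frequency; the window must hold >= 20 cycles.
#' @param n_neighbors one-sided width of the noise-floor neighborhood, bins.
#' @return list with `magnitude`, `noise_floor`, `bin_hz`, `resolution_hz`.
#' @export
segment_component <- function(avg, times, rate, window, target_hz,
                              n_neighbors = 10) {
  sel <- which(times >= window[1] - 1e-9 & times < window[2] - 1e-9)
  n <- length(sel)
  if ((n / rate) * target_hz < 20)
    stop("window too short: fewer than 20 cycles of ", target_hz, " Hz")
  x <- avg[sel]
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))   # periodic Hann
  X <- stats::fft(x * w)
  freq <- (0:(n - 1)) * rate / n
  half <- 2:floor(n / 2)
  k <- half[which.min(abs(freq[half] - target_hz))]
  amp <- 2 * Mod(X) / sum(w)
  nb <- setdiff(intersect((k - n_neighbors):(k + n_neighbors), half),
                (k - 2):(k + 2))
  list(magnitude = amp[k], noise_floor = mean(amp[nb]),
       bin_hz = freq[k], resolution_hz = rate / n)
}

# default segment windows: 10-90 ms after each probe onset (probe1 at 0 s,
# probe2 at 0.251 s in the stimulus sequence), identical post-onset alignment
ffr_segment_windows <- function(probe1_onset = 0, probe2_onset = 0.251,
                                post_onset = c(0.01, 0.09)) {
  list(probe1 = probe1_onset + post_onset,
       probe2 = probe2_onset + post_onset)
}

#' Forward-masking residuals of the FFR decomposition
#'
#' Subtracts the aligned probe-2 segment from the probe-1 segment in the
#' time domain, then reads the spectral magnitude of the residual at 500 Hz
#' (difference average: the adaptable "neural" TFS component; the
#' masking-insensitive preneural part cancels) and 1000 Hz (sum average
#' rectification component).
#'
#' @param decomp output of [polarity_decompose()].
#' @param windows segment windows from [ffr_segment_windows()].
#' @param diff_hz,sum_hz analysis frequencies (500 / 1000).
#' @return list with `r_d`, `r_s` (residual magnitudes), noise floors.
#' @export
forward_masking_residual <- function(decomp, windows = ffr_segment_windows(),
                                     diff_hz = 500, sum_hz = 1000) {
  i1 <- which(decomp$times >= windows$probe1[1] - 1e-9 &
                decomp$times < windows$probe1[2] - 1e-9)
  i2 <- which(decomp$times >= windows$probe2[1] - 1e-9 &
                decomp$times < windows$probe2[2] - 1e-9)
  if (length(i1) != length(i2))
    stop("probe segment windows are misaligned")
  resid_d <- decomp$diff
  resid_d[i1] <- decomp$diff[i1] - decomp$diff[i2]
  resid_s <- decomp$sum
  resid_s[i1] <- decomp$sum[i1] - decomp$sum[i2]
  rd <- segment_component(resid_d, decomp$times, decomp$rate,
                          windows$probe1, diff_hz)
  rs <- segment_component(resid_s, decomp$times, decomp$rate,
                          windows$probe1, sum_hz)
  list(r_d = rd$magnitude, r_d_noise_floor = rd$noise_floor,
       r_s = rs$magnitude, r_s_noise_floor = rs$noise_floor)
}

#' Partial-suppression ratios d2/d1 and s2/s1
#'
#' A ratio near 1 means the forward masker barely suppressed the component
#' (preneural-dominated); a ratio well below 1 indicates a neural-dominated
#' response. Undefined (NA) when the denominator is at or below its noise
#' floor.
#'
#' @param d1,d2,s1,s2 component magnitudes with their noise floors, as
#'   returned by [segment_component()].
#' @return list with `ratio_d`, `ratio_s` (possibly NA).
#' @export
partial_suppression_ratio <- function(d1, d2, s1, s2) {
  rd <- if (d1$magnitude > d1$noise_floor) d2$magnitude / d1$magnitude else NA_real_
  rs <- if (s1$magnitude > s1$noise_floor) s2$magnitude / s1$magnitude else NA_real_
  list(ratio_d = rd, ratio_s = rs)
}

#' Full FFR metric set for one subject
#'
#' @param epochs polarity-labelled FFR [epoch_array()].
#' @param windows segment windows from [ffr_segment_windows()].
#' @param seed polarity-balancing seed.
#' @return list with `d1`, `d2`, `s1`, `s2` magnitudes, residuals `r_d`,
#'   `r_s`, suppression ratios, and noise floors.
#' @export
ffr_metrics <- function(epochs, windows = ffr_segment_windows(), seed = 1) {
  dec <- polarity_decompose(epochs, seed = seed)
  d1 <- segment_component(dec$diff, dec$times, dec$rate, windows$probe1, 500)
  d2 <- segment_component(dec$diff, dec$times, dec$rate, windows$probe2, 500)
  s1 <- segment_component(dec$sum, dec$times, dec$rate, windows$probe1, 1000)
  s2 <- segment_component(dec$sum, dec$times, dec$rate, windows$probe2, 1000)
  res <- forward_masking_residual(dec, windows)
  ratios <- partial_suppression_ratio(d1, d2, s1, s2)
  list(d1 = d1$magnitude, d2 = d2$magnitude,
       s1 = s1$magnitude, s2 = s2$magnitude,
       r_d = res$r_d, r_s = res$r_s,
       ratio_d = ratios$ratio_d, ratio_s = ratios$ratio_s,
       noise_floors = list(d1 = d1$noise_floor, d2 = d2$noise_floor,
                           s1 = s1$noise_floor, s2 = s2$noise_floor,
                           r_d = res$r_d_noise_floor,
                           r_s = res$r_s_noise_floor),
       n_per_polarity = dec$n_per_polarity)
}
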