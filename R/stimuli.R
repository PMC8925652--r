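# Stimulus synthesis for the TFS assay battery.
#
# All paradigms render to a calibrated stereo_waveform. Interaural delays are
# realized as sub-sample fractional delays via a frequency-domain phase shift,
# so the audio sampling rate never limits ITD resolution.

#' Default synthesis settings shared across paradigms
#'
#' @param fs sampling rate, samples/s.
#' @param calibration_db_spl dB SPL of a full-scale sinusoid.
#' @return a list of defaults consumed by the `synth_*` functions.
#' @export
stim_spec <- function(fs = 48000, calibration_db_spl = 100) {
  list(fs = fs, calibration_db_spl = calibration_db_spl)
}

# raised-cosine on/off ramps, ramp_s at each end
apply_ramps <- function(x, fs, ramp_s) {
  if (ramp_s <= 0) return(x)
  n <- length(x)
  nr <- round(ramp_s * fs)
  stopifnot(2 * nr <= n)
  if (nr < 2) return(x)
  w <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / (nr - 1)))
  x[1:nr] <- x[1:nr] * w
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(w)
  x
}

# sub-sample delay by delay_s (positive = later arrival) via FFT phase shift
frac_delay <- function(x, fs, delay_s) {
  if (delay_s == 0) return(x)
  n <- length(x)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  f <- k * fs / n
  ph <- exp(-2i * pi * f * delay_s)
  if (n %% 2 == 0) ph[n / 2 + 1] <- Re(ph[n / 2 + 1])  # keep Nyquist real
  Re(stats::fft(stats::fft(x) * ph, inverse = TRUE) / n)
}

#' Synthesize the FM-detection target tone
#'
#' A 500-Hz tone, sinusoidally frequency modulated at 2 Hz with peak
#' frequency deviation `depth_hz`, 500 ms long, 5-ms raised-cosine ramps,
#' 70 dB SPL, presented diotically. `depth_hz = 0` yields the pure-tone
#' reference interval.
#'
#' @param depth_hz peak frequency deviation in Hz (>= 0, < carrier).
#' @param carrier_hz carrier frequency (default 500).
#' @param fm_rate_hz modulation rate (default 2).
#' @param duration_s tone duration (default 0.5).
#' @param level_db_spl presentation level (default 70).
#' @param ramp_s rise/fall time (default 0.005).
#' @param spec a [stim_spec()] list.
#' @return a `stereo_waveform`.
#' @export
synth_fm_tone <- function(depth_hz, carrier_hz = 500, fm_rate_hz = 2,
                          duration_s = 0.5, level_db_spl = 70,
                          ramp_s = 0.005, spec = stim_spec()) {
  stopifnot(depth_hz >= 0)
  if (depth_hz >= carrier_hz)
    stop("FM depth >= carrier frequency is non-physical")
  fs <- spec$fs
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  # instantaneous frequency carrier + depth*cos(2 pi fm t); phase is its integral
  phase <- 2 * pi * carrier_hz * t +
    (depth_hz / fm_rate_hz) * sin(2 * pi * fm_rate_hz * t)
  a <- db_spl_to_amplitude(level_db_spl, spec$calibration_db_spl)
  x <- apply_ramps(a * sin(phase), fs, ramp_s)
  stereo_waveform(x, x, fs, spec$calibration_db_spl,
                  events = data.frame(time = 0, label = "tone_on"),
                  paradigm = "fm",
                  params = list(depth_hz = depth_hz, carrier_hz = carrier_hz,
                                fm_rate_hz = fm_rate_hz,
                                level_db_spl = level_db_spl))
}

#' Synthesize an ITD-detection trial: two tone bursts with opposite leads
#'
#' Two consecutive 400-ms, 500-Hz tone bursts at 70 dB SPL with 20-ms ramps.
#' In the first burst, `first_lead` receives the signal `itd_us/2`
#' microseconds early and the other ear `itd_us/2` late; the lead switches
#' ears for the second burst, so the listener judges the direction of the
#' jump.
#'
#' @param itd_us interaural time difference in microseconds (>= 0).
#' @param first_lead `"left"` or `"right"`: leading ear in the first burst.
#' @param carrier_hz carrier frequency (default 500).
#' @param burst_s burst duration (default 0.4).
#' @param gap_s silent gap between bursts (default 0; the source paradigm
#'   does not specify one).
#' @param level_db_spl presentation level (default 70).
#' @param ramp_s rise/fall time (default 0.02).
#' @param spec a [stim_spec()] list.
#' @return a `stereo_waveform` with burst-onset events.
#' @export
synth_itd_burst_pair <- function(itd_us, first_lead = c("left", "right"),
                                 carrier_hz = 500, burst_s = 0.4, gap_s = 0,
                                 level_db_spl = 70, ramp_s = 0.02,
                                 spec = stim_spec()) {
  first_lead <- match.arg(first_lead)
  stopifnot(itd_us >= 0)
  if (itd_us * 1e-6 > burst_s)
    stop("ITD exceeds burst duration")
  fs <- spec$fs
  t <- seq(0, burst_s - 1 / fs, by = 1 / fs)
  a <- db_spl_to_amplitude(level_db_spl, spec$calibration_db_spl)
  mono <- apply_ramps(a * sin(2 * pi * carrier_hz * t), fs, ramp_s)
  d <- itd_us * 1e-6 / 2
  lead  <- frac_delay(mono, fs, -d)   # arrives earlier
  lag   <- frac_delay(mono, fs, +d)
  gap <- numeric(round(gap_s * fs))
  if (first_lead == "left") {
    left  <- c(lead, gap, lag)
    right <- c(lag, gap, lead)
  } else {
    left  <- c(lag, gap, lead)
    right <- c(lead, gap, lag)
  }
  # fractional delay of a ramped burst can overshoot |1| by a sliver; it
  # cannot here because levels are well below full scale
  ev <- data.frame(time = c(0, burst_s + gap_s),
                   label = c("burst1_on", "burst2_on"))
  stereo_waveform(left, right, fs, spec$calibration_db_spl, events = ev,
                  paradigm = "itd_burst",
                  params = list(itd_us = itd_us, first_lead = first_lead,
                                level_db_spl = level_db_spl))
}

#' Trough times of the 40.8-Hz amplitude modulation
#'
#' With the envelope convention `e(t) = (1 - cos(2 pi f_am t))/2`, troughs
#' fall exactly at integer multiples of `1/f_am`; the ITD jump is placed at
#' the trough nearest `near_s`.
#'
#' @param near_s target time (s).
#' @param am_rate_hz modulation rate (default 40.8).
#' @return the trough time in seconds.
#' @export
am_trough_near <- function(near_s, am_rate_hz = 40.8) {
  round(near_s * am_rate_hz) / am_rate_hz
}

#' Synthesize a cortical ITD-jump trial
#'
#' A 1.5-s, 500-Hz tone, 100%-depth amplitude modulated at 40.8 Hz, with an
#' ITD of `jump_us/2` leading one ear before the jump and `jump_us/2`
#' leading the other ear afterwards (a total interaural jump of `jump_us`).
#' The jump is placed at the modulation trough nearest 1.0 s so stimulus
#' amplitude is (essentially) zero at the switch, suppressing monaural cues.
#'
#' @param jump_us total ITD jump in microseconds (> 0).
#' @param direction `"LR"` (left leads first) or `"RL"`.
#' @param carrier_hz carrier (default 500).
#' @param am_rate_hz modulation rate (default 40.8).
#' @param am_depth modulation depth (default 1; a warning is issued for
#'   depth < 1 because the trough is then nonzero).
#' @param duration_s trial duration (default 1.5).
#' @param jump_near_s nominal jump time (default 1.0).
#' @param level_db_spl presentation level (default 70).
#' @param ramp_s overall on/off ramp (default 0.005).
#' @param spec a [stim_spec()] list.
#' @return a `stereo_waveform` with an `itd_jump` event.
#' @export
synth_itd_jump_trial <- function(jump_us, direction = c("LR", "RL"),
                                 carrier_hz = 500, am_rate_hz = 40.8,
                                 am_depth = 1, duration_s = 1.5,
                                 jump_near_s = 1.0, level_db_spl = 70,
                                 ramp_s = 0.005, spec = stim_spec()) {
  direction <- match.arg(direction)
  stopifnot(jump_us > 0, am_depth >= 0, am_depth <= 1)
  if (am_depth < 1)
    warning("modulation depth < 1: the jump trough is nonzero")
  fs <- spec$fs
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  t_jump <- am_trough_near(jump_near_s, am_rate_hz)
  a <- db_spl_to_amplitude(level_db_spl, spec$calibration_db_spl)
  # pre-jump interaural ITD is jump_us/2 (e.g. the 20-us condition starts at
  # 10 us one ear leading), so each channel is shifted by jump_us/4
  d <- jump_us * 1e-6 / 4
  render_ch <- function(d_pre, d_post) {
    sig <- function(dd) {
      # depth-1 convention: env = (1 - cos)/2, troughs at t = dd + k/f_am
      env <- (1 - am_depth) + am_depth * (1 - cos(2 * pi * am_rate_hz * (t - dd))) / 2
      env * sin(2 * pi * carrier_hz * (t - dd))
    }
    pre <- sig(d_pre); post <- sig(d_post)
    ifelse(t < t_jump, pre, post)
  }
  if (direction == "LR") {           # left leads (earlier) before the jump
    left  <- render_ch(-d, +d)
    right <- render_ch(+d, -d)
  } else {
    left  <- render_ch(+d, -d)
    right <- render_ch(-d, +d)
  }
  left  <- apply_ramps(a * left, fs, ramp_s)
  right <- apply_ramps(a * right, fs, ramp_s)
  ev <- data.frame(time = c(0, t_jump, duration_s),
                   label = c("stim_on", "itd_jump", "stim_off"))
  stereo_waveform(left, right, fs, spec$calibration_db_spl, events = ev,
                  paradigm = "itd_jump",
                  params = list(jump_us = jump_us, direction = direction,
                                am_rate_hz = am_rate_hz, t_jump = t_jump,
                                level_db_spl = level_db_spl))
}

#' Synthesize the forward-masked FFR stimulus sequence
#'
#' Probe (100 ms, 75 dB SPL) + 50-ms gap + masker (100 ms, 85 dB SPL) +
#' 1-ms gap + probe (100 ms, 75 dB SPL), all 500-Hz tones with 5-ms ramps;
#' total duration 0.351 s. `polarity = -1` is the sample-wise negation of
#' `polarity = +1` (polarity is alternated across trials in the recording
#' paradigm).
#'
#' @param polarity +1 or -1.
#' @param carrier_hz carrier (default 500).
#' @param probe_level_db_spl,masker_level_db_spl segment levels (75 / 85).
#' @param spec a [stim_spec()] list.
#' @return a `stereo_waveform` (diotic) with segment-onset events.
#' @export
synth_ffr_sequence <- function(polarity = 1, carrier_hz = 500,
                               probe_level_db_spl = 75,
                               masker_level_db_spl = 85,
                               spec = stim_spec()) {
  stopifnot(polarity %in% c(-1, 1))
  fs <- spec$fs
  seg <- function(dur, level) {
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    a <- db_spl_to_amplitude(level, spec$calibration_db_spl)
    apply_ramps(a * sin(2 * pi * carrier_hz * t), fs, 0.005)
  }
  gap <- function(dur) numeric(round(dur * fs))
  x <- polarity * c(seg(0.1, probe_level_db_spl), gap(0.05),
                    seg(0.1, masker_level_db_spl), gap(0.001),
                    seg(0.1, probe_level_db_spl))
  ev <- data.frame(time = c(0, 0.15, 0.251),
                   label = c("probe1_on", "masker_on", "probe2_on"))
  stereo_waveform(x, x, fs, spec$calibration_db_spl, events = ev,
                  paradigm = "ffr_sequence",
                  params = list(polarity = polarity, carrier_hz = carrier_hz))
}

#' Equivalent rectangular bandwidth of the auditory filter at f
#'
#' `ERB(f) = 24.7 (4.37 f/1000 + 1)` Hz.
#'
#' @param f_hz center frequency in Hz.
#' @return bandwidth in Hz.
#' @export
erb_hz <- function(f_hz) 24.7 * (4.37 * f_hz / 1000 + 1)

#' Synthesize the supplementary AM-detection trial
#'
#' A 500-Hz-wide Gaussian noise band centered at `center_hz`, sinusoidally
#' amplitude modulated at 19 Hz with the given depth, plus two unmodulated
#' pure-tone flankers at `center_hz +/- 2 ERB(center_hz)` to discourage
#' off-frequency listening; all components at 75 dB SPL. `depth = 0` renders
#' the statistically identical unmodulated reference.
#'
#' @param depth AM depth in \[0, 1\].
#' @param center_hz noise-band center (4000 or 8000 by default usage).
#' @param seed RNG seed for the noise band.
#' @param duration_s trial duration (default 0.5).
#' @param bandwidth_hz noise bandwidth (default 500).
#' @param am_rate_hz modulation rate (default 19).
#' @param level_db_spl per-component level (default 75).
#' @param ramp_s on/off ramp (default 0.005).
#' @param flankers include the two pure-tone flankers (default TRUE; set
#'   FALSE to inspect the modulated noise band alone).
#' @param spec a [stim_spec()] list.
#' @return a `stereo_waveform` (diotic).
#' @export
synth_am_noise_trial <- function(depth, center_hz = 4000, seed = 1,
                                 duration_s = 0.5, bandwidth_hz = 500,
                                 am_rate_hz = 19, level_db_spl = 75,
                                 ramp_s = 0.005, flankers = TRUE,
                                 spec = stim_spec()) {
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  fs <- spec$fs
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  noise <- local_seed(seed, {
    # spectral brick-wall band: random phases, unit magnitude in band
    f <- (0:(n - 1)) * fs / n
    in_band <- f >= center_hz - bandwidth_hz / 2 & f <= center_hz + bandwidth_hz / 2
    spec_c <- complex(modulus = 0, argument = 0, length.out = n)
    ph <- stats::runif(sum(in_band), 0, 2 * pi)
    spec_c[in_band] <- complex(modulus = 1, argument = ph)
    x <- Re(stats::fft(spec_c, inverse = TRUE))
    x / stats::sd(x)                                   # unit RMS
  })
  # scale so the noise band has the RMS of a sinusoid at level_db_spl
  a <- db_spl_to_amplitude(level_db_spl, spec$calibration_db_spl)
  noise <- noise * a / sqrt(2)
  mod <- (1 + depth * sin(2 * pi * am_rate_hz * t)) / sqrt(1 + depth^2 / 2)
  target <- noise * mod
  erb2 <- 2 * erb_hz(center_hz)
  flank <- if (flankers)
    a * (sin(2 * pi * (center_hz - erb2) * t) +
           sin(2 * pi * (center_hz + erb2) * t)) else 0
  x <- apply_ramps(target + flank, fs, ramp_s)
  peak <- max(abs(x))
  if (peak > 1) x <- x / (peak * 1.0001)               # headroom guard
  stereo_waveform(x, x, fs, spec$calibration_db_spl,
                  events = data.frame(time = 0, label = "noise_on"),
                  paradigm = "am_noise",
                  params = list(depth = depth, center_hz = center_hz,
                                am_rate_hz = am_rate_hz, seed = seed,
                                flanker_offset_hz = erb2))
}
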