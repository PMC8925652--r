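# Stimulus synthesis: calibration, FM structure, interaural delays, the
# jump-at-trough convention, FFR sequence timing, and AM noise.

spec16 <- stim_spec(fs = 16000)

test_that("level calibration maps dB SPL to linear amplitude", {
  expect_equal(db_spl_to_amplitude(100, 100), 1.0)
  expect_equal(db_spl_to_amplitude(80, 100), 0.1)
  expect_equal(db_spl_to_amplitude(70, 100), 10^(-1.5))
  expect_error(db_spl_to_amplitude(101, 100), "clip")
})

test_that("zero-depth FM tone is the pure-tone reference with exact ramps", {
  wf <- synth_fm_tone(0, spec = spec16)
  fs <- spec16$fs
  t <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
  a <- 10^((70 - 100) / 20)
  ref <- a * sin(2 * pi * 500 * t)
  nr <- round(0.005 * fs)
  w <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / (nr - 1)))
  ref[1:nr] <- ref[1:nr] * w
  ref[(length(ref) - nr + 1):length(ref)] <-
    ref[(length(ref) - nr + 1):length(ref)] * rev(w)
  expect_lt(max(abs(wf$left - ref)), 1e-6)
  expect_identical(wf$left, wf$right)
})

test_that("FM instantaneous frequency spans carrier +/- depth", {
  wf <- synth_fm_tone(13, spec = spec16)
  fi <- inst_freq_hz(wf$left, spec16$fs)
  mid <- fi[100:7900]         # away from the ramps
  expect_equal(max(mid), 513, tolerance = 0.1)
  expect_equal(min(mid), 487, tolerance = 0.1)
  expect_error(synth_fm_tone(500), "non-physical")
})

test_that("FM spectrum has the carrier peak and 2-Hz-spaced sidebands", {
  # shallow modulation: carrier dominates (J0 near 1)
  wf1 <- synth_fm_tone(1, duration_s = 4, ramp_s = 0, spec = spec16)
  sp1 <- amp_spectrum(wf1$left, spec16$fs)
  expect_equal(sp1$f[which.max(sp1$a)], 500)

  # deeper modulation: Bessel sidebands at multiples of the 2-Hz rate
  wf <- synth_fm_tone(5, duration_s = 4, ramp_s = 0, spec = spec16)
  sp <- amp_spectrum(wf$left, spec16$fs)
  peak_at <- function(f0) sp$a[which.min(abs(sp$f - f0))]
  floor_level <- stats::median(sp$a)
  expect_gt(peak_at(502), 20 * floor_level)
  expect_gt(peak_at(498), 20 * floor_level)
  expect_gt(peak_at(504), 20 * floor_level)
  expect_lt(peak_at(501), peak_at(502) / 20)  # no sideband between multiples
})

test_that("ITD bursts carry the requested interaural lag with sign flip", {
  wf0 <- synth_itd_burst_pair(0, "left", spec = spec16)
  expect_identical(wf0$left, wf0$right)

  wf <- synth_itd_burst_pair(89, "left", spec = spec16)
  n_burst <- round(0.4 * spec16$fs)
  lag1 <- xcorr_lag_us(wf$left[1:n_burst], wf$right[1:n_burst], spec16$fs)
  lag2 <- xcorr_lag_us(wf$left[(n_burst + 1):(2 * n_burst)],
                       wf$right[(n_burst + 1):(2 * n_burst)], spec16$fs)
  grid_us <- 1e6 / (spec16$fs * 10)    # one sample of the upsampled grid
  expect_lt(abs(lag1 - 89), grid_us + 1e-9)
  expect_lt(abs(lag2 + 89), grid_us + 1e-9)
})

test_that("switching the leading ear mirrors the channels exactly", {
  a <- synth_itd_burst_pair(500, "left", spec = spec16)
  b <- synth_itd_burst_pair(500, "right", spec = spec16)
  expect_equal(a$left, b$right, tolerance = 1e-12)
  expect_equal(a$right, b$left, tolerance = 1e-12)
  expect_error(synth_itd_burst_pair(5e5, "left", spec = spec16), "exceeds")
})

test_that("ITD jump sits at the AM trough nearest 1 s with near-zero envelope", {
  expect_equal(am_trough_near(1.0), 41 / 40.8)
  wf <- synth_itd_jump_trial(540, "LR", spec = spec16)
  t_jump <- wf$events$time[wf$events$label == "itd_jump"]
  expect_equal(t_jump, 41 / 40.8)
  env <- hilbert_envelope(wf$left)
  i_jump <- round(t_jump * spec16$fs) + 1
  expect_lt(env[i_jump], 0.01 * max(env))
})

test_that("ITD jump flips the interaural lag sign and keeps its magnitude", {
  # pre-jump ITD is jump/2 = 270 us (one ear leading), flipping to -270 us
  wf <- synth_itd_jump_trial(540, "LR", spec = spec16)
  fs <- spec16$fs
  i_jump <- round(41 / 40.8 * fs)
  pre <- 1:(i_jump - round(0.05 * fs))
  post <- (i_jump + round(0.05 * fs)):length(wf$left)
  lag_pre <- xcorr_lag_us(wf$left[pre], wf$right[pre], fs)
  lag_post <- xcorr_lag_us(wf$left[post], wf$right[post], fs)
  grid_us <- 1e6 / (fs * 10)
  # the modulated envelope weights the cross-correlation peak slightly, so
  # allow a couple of upsampled samples beyond the grid
  expect_lt(abs(lag_pre - 270), 3 * grid_us)
  expect_lt(abs(lag_post + 270), 3 * grid_us)
  expect_warning(synth_itd_jump_trial(540, "LR", am_depth = 0.8,
                                      spec = spec16), "trough")
})

test_that("FFR sequence has the printed segment timing and polarity symmetry", {
  wp <- synth_ffr_sequence(+1, spec = spec16)
  wn <- synth_ffr_sequence(-1, spec = spec16)
  expect_equal(wf_duration(wp), 0.351, tolerance = 1e-9)
  expect_equal(wn$left, -wp$left, tolerance = 1e-15)
  fs <- spec16$fs
  rms <- function(i) sqrt(mean(wp$left[i]^2))
  probe1 <- (round(0.02 * fs)):(round(0.08 * fs))     # ramp-free cores
  masker <- (round(0.17 * fs)):(round(0.23 * fs))
  expect_equal(rms(masker) / rms(probe1), 10^(10 / 20), tolerance = 1e-3)
  expect_equal(wp$events$time, c(0, 0.15, 0.251))
})

test_that("AM noise trial: ERB flanker placement and 19-Hz envelope peak", {
  expect_equal(erb_hz(4000), 456.456, tolerance = 1e-3)
  wff <- synth_am_noise_trial(1, center_hz = 4000, seed = 3, spec = spec16)
  expect_equal(wff$params$flanker_offset_hz, 2 * erb_hz(4000))

  # envelope of the modulated noise band itself (flankers excluded)
  wf <- synth_am_noise_trial(1, center_hz = 4000, seed = 3, flankers = FALSE,
                             spec = spec16)
  env <- hilbert_envelope(wf$left)
  sp <- amp_spectrum(env - mean(env), spec16$fs)
  sel <- sp$f > 2 & sp$f < 100
  expect_equal(sp$f[sel][which.max(sp$a[sel])], 19, tolerance = 2.1)

  ref <- synth_am_noise_trial(0, center_hz = 4000, seed = 3, flankers = FALSE,
                              spec = spec16)
  env0 <- hilbert_envelope(ref$left)
  sp0 <- amp_spectrum(env0 - mean(env0), spec16$fs)
  at19 <- function(s) s$a[which.min(abs(s$f - 19))]
  expect_gt(at19(sp), 5 * at19(sp0))
  expect_error(synth_am_noise_trial(1.2), "0, 1")
})

test_that("rendered waveforms stay within full scale across paradigms", {
  wfs <- list(synth_fm_tone(10, spec = spec16),
              synth_itd_burst_pair(300, "right", spec = spec16),
              synth_itd_jump_trial(20, "RL", spec = spec16),
              synth_ffr_sequence(-1, spec = spec16),
              synth_am_noise_trial(0.5, 8000, seed = 9, spec = spec16))
  for (wf in wfs)
    expect_lte(max(abs(c(wf$left, wf$right))), 1)
})
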