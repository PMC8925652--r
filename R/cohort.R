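# Synthetic cohorts with known latent parameters.
#
# Each simulated subject carries independent sensory (psychometric midpoint),
# nonsensory (lapse rate), anatomical (EEG gain), and physiological (latency
# shift, ITD-response sigmoid, FFR component amplitudes) latents. Behavioral
# trial logs, cortical ITD-jump epochs and forward-masked FFR epochs are
# rendered from these latents so every pipeline stage can be checked against
# ground truth. The EEG gain scales the signal BEFORE sensor noise is added,
# so it changes the single-trial SNR and hence the ITC - the anatomy
# confound that motivates the latency and normalized-slope metrics.

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the study conditions of the source paradigm: n = 32
#' subjects, ITD thresholds spanning roughly 21-39 dB re 1 us and FM
#' thresholds 7-22 dB re 1 Hz, 1200 cortical trials (300 per ITD-jump
#' condition), 8000 alternating-polarity FFR trials, and a lapse-rate
#' distribution calibrated so the nonsensory score accounts for roughly a
#' third of raw ITD threshold variance.
#'
#' @param n_subjects cohort size (>= 3).
#' @param theta_b_mean,theta_b_sd binaural (ITD) sensory midpoint, dB re 1 us.
#' @param theta_m_mean,theta_m_sd monaural (FM) sensory midpoint, dB re 1 Hz.
#' @param spread_db psychometric spread (dB) for both tasks.
#' @param lapse_max,lapse_shape1,lapse_shape2 lapse rate lambda =
#'   `lapse_max * Beta(shape1, shape2)`.
#' @param g_sdlog SD of log EEG gain (lognormal, median 1).
#' @param tau_coupling_s,tau_noise_sd_s latency shift tau (s) =
#'   coupling * z(theta_b) + Gaussian noise: worse behavioral sensitivity
#'   gives longer cortical latency.
#' @param itd_mid_log0,itd_mid_coupling,itd_mid_noise_sd log-ITD midpoint of
#'   the cortical response sigmoid (base log(60 us), coupled to theta_b).
#' @param itd_steep_log sigmoid steepness in log-ITD units.
#' @param evoked_amp_uv,onset_amp_uv,offset_amp_uv,assr_amp_uv kernel and
#'   steady-state amplitudes at unit gain (uV).
#' @param pink_sd_uv,white_sd_uv cortical sensor-noise amplitudes (uV).
#' @param ffr_An_med,ffr_Ac_med,ffr_A_sdlog,ffr_alpha_shape1,ffr_alpha_shape2
#'   FFR neural/preneural amplitude (uV, lognormal medians) and masking
#'   factor alpha ~ Beta distribution.
#' @param ffr_noise_sd_uv per-trial FFR noise SD (uV).
#' @param n_cortical_trials total cortical trials (split over 4 conditions).
#' @param n_ffr_trials total FFR trials (alternating polarity, even).
#' @param fm_blocks,itd_blocks behavioral blocks per task (per ear for FM).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 32,
                          theta_b_mean = 29, theta_b_sd = 4.5,
                          theta_m_mean = 14, theta_m_sd = 3.5,
                          spread_db = 2,
                          lapse_max = 0.3, lapse_shape1 = 2,
                          lapse_shape2 = 3,
                          g_sdlog = 0.4,
                          tau_coupling_s = 0.010, tau_noise_sd_s = 0.017,
                          itd_mid_log0 = log(60), itd_mid_coupling = 0.25,
                          itd_mid_noise_sd = 0.43,
                          itd_steep_log = 0.45,
                          evoked_amp_uv = 5, onset_amp_uv = 5,
                          offset_amp_uv = 2.5, assr_amp_uv = 1,
                          pink_sd_uv = 6, white_sd_uv = 3,
                          ffr_An_med = 0.10, ffr_Ac_med = 0.20,
                          ffr_A_sdlog = 0.3,
                          ffr_alpha_shape1 = 8, ffr_alpha_shape2 = 2,
                          ffr_noise_sd_uv = 2,
                          n_cortical_trials = 1200, n_ffr_trials = 8000,
                          fm_blocks = 4, itd_blocks = 8) {
  stopifnot(n_subjects >= 3, theta_b_sd >= 0, theta_m_sd >= 0,
            n_ffr_trials %% 2 == 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Draw a cohort of latent subjects
#'
#' Reproducible: the same (config, seed) always yields the same cohort.
#' Coupling structure: cortical latency shift and the ITD-response sigmoid
#' midpoint increase with the binaural sensory parameter theta_b (worse
#' behavioral sensitivity goes with longer latency and shallower growth),
#' while the EEG gain and the lapse rate are independent of theta_b.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data.frame of latents, one row per subject (the ground-truth
#'   table).
#' @export
sample_cohort <- function(config, seed = 1) {
  local_seed(seed, {
    n <- config$n_subjects
    theta_b <- stats::rnorm(n, config$theta_b_mean, config$theta_b_sd)
    theta_m <- stats::rnorm(n, config$theta_m_mean, config$theta_m_sd)
    z_b <- if (config$theta_b_sd > 0)
      (theta_b - config$theta_b_mean) / config$theta_b_sd else rep(0, n)
    lapse <- config$lapse_max *
      stats::rbeta(n, config$lapse_shape1, config$lapse_shape2)
    if (config$lapse_max == 0) lapse <- rep(0, n)
    g <- exp(stats::rnorm(n, 0, config$g_sdlog))
    tau <- config$tau_coupling_s * z_b +
      stats::rnorm(n, 0, config$tau_noise_sd_s)
    itd_mid_log <- config$itd_mid_log0 + config$itd_mid_coupling * z_b +
      stats::rnorm(n, 0, config$itd_mid_noise_sd)
    itd_steep <- rep(config$itd_steep_log, n)
    ffr_An <- exp(stats::rnorm(n, log(config$ffr_An_med), config$ffr_A_sdlog))
    ffr_Ac <- exp(stats::rnorm(n, log(config$ffr_Ac_med), config$ffr_A_sdlog))
    ffr_alpha <- stats::rbeta(n, config$ffr_alpha_shape1,
                              config$ffr_alpha_shape2)
    data.frame(subject = seq_len(n), theta_b = theta_b, theta_m = theta_m,
               lapse = lapse, eeg_gain = g, eeg_latency_shift = tau,
               itd_mid_log = itd_mid_log, itd_steep = itd_steep,
               ffr_A_neural = ffr_An, ffr_A_preneural = ffr_Ac,
               ffr_alpha = ffr_alpha)
  })
}

#' Render a subject's behavioral blocks for one task
#'
#' Drives the staircase engine with an observer built from the subject's
#' latent sensory midpoint and lapse rate. FM runs 4 blocks per ear (8
#' tracks); ITD runs 8 blocks.
#'
#' @param subject one row of a [sample_cohort()] table.
#' @param task `"fm"` or `"itd"`.
#' @param config a [cohort_config()].
#' @param seed integer seed (block seeds are derived from it).
#' @return list of `staircase_run`s with catch trials flagged.
#' @export
render_behavior <- function(subject, task = c("fm", "itd"),
                            config = cohort_config(), seed = 1) {
  task <- match.arg(task)
  if (task == "fm") {
    obs <- psychometric_observer(subject$theta_m, config$spread_db,
                                 subject$lapse)
    cfg <- fm_staircase_config()
    n_blocks <- 2 * config$fm_blocks       # two ears
  } else {
    obs <- psychometric_observer(subject$theta_b, config$spread_db,
                                 subject$lapse)
    cfg <- itd_staircase_config()
    n_blocks <- config$itd_blocks
  }
  lapply(seq_len(n_blocks), function(b)
    run_staircase(obs, cfg, seed = derive_seed(seed, subject$subject, b,
                                               match(task, c("fm", "itd")))))
}

# pink (1/f amplitude) noise, trials in columns; sd set in the time domain
pink_noise_matrix <- function(nt, n_trials, sd) {
  if (sd == 0) return(matrix(0, nt, n_trials))
  k <- 1:floor(nt / 2)
  spec <- matrix(0i, nt, n_trials)
  z <- matrix(stats::rnorm(length(k) * n_trials) +
                1i * stats::rnorm(length(k) * n_trials), length(k), n_trials)
  spec[k + 1, ] <- z / sqrt(k)
  x <- Re(stats::mvfft(spec, inverse = TRUE))
  x <- x / stats::sd(as.vector(x))
  x * sd
}

#' Render a subject's cortical ITD-jump epochs
#'
#' Forward model per trial: `gain * [a(ITD) * (N1 + P2 kernels at nominal
#' latency + tau) + offset kernel] + ASSR sinusoid + 1/f noise + white
#' noise`, where `a(ITD)` is a logistic function of log ITD with the
#' subject's midpoint and steepness. The gain multiplies the signal before
#' the (fixed-amplitude) sensor noise, so it alters SNR and therefore ITC.
#'
#' @param subject one row of a [sample_cohort()] table.
#' @param conditions ITD-jump sizes in us.
#' @param n_trials_per_cond trials per condition.
#' @param seed integer seed.
#' @param config a [cohort_config()].
#' @param fs sampling rate (default 256).
#' @param window epoch window around the jump event (s).
#' @return an [epoch_array()] with one channel (`Cz`) and condition labels.
#' @export
render_cortical_eeg <- function(subject, conditions = c(20, 60, 180, 540),
                                n_trials_per_cond = 300, seed = 1,
                                config = cohort_config(), fs = 256,
                                window = c(-0.5, 0.7)) {
  local_seed(derive_seed(seed, subject$subject, 7001), {
    nt <- round((window[2] - window[1]) * fs) + 1
    t <- window[1] + (0:(nt - 1)) / fs
    gauss <- function(mu, sigma = 0.025) exp(-(t - mu)^2 / (2 * sigma^2))
    tau <- subject$eeg_latency_shift
    # jump placed at the AM trough nearest 1 s of a 1.5-s trial
    t_jump <- am_trough_near(1.0)
    t_off <- 1.5 - t_jump
    jump_kernel <- -config$evoked_amp_uv * gauss(0.10 + tau) +
      config$evoked_amp_uv * gauss(0.20 + tau)
    offset_kernel <- -config$offset_amp_uv * gauss(t_off + 0.10 + tau) +
      config$offset_amp_uv * gauss(t_off + 0.20 + tau)
    assr <- config$assr_amp_uv * sin(2 * pi * 40.8 * (t + t_jump)) *
      (t <= t_off)
    a_itd <- stats::plogis((log(conditions) - subject$itd_mid_log) /
                             subject$itd_steep)
    n_total <- n_trials_per_cond * length(conditions)
    labels <- rep(conditions, each = n_trials_per_cond)
    data <- array(NA_real_, c(n_total, 1, nt))
    g <- subject$eeg_gain
    for (ci in seq_along(conditions)) {
      rows <- (ci - 1) * n_trials_per_cond + seq_len(n_trials_per_cond)
      sig <- g * (a_itd[ci] * jump_kernel + offset_kernel) + g * assr
      noise <- pink_noise_matrix(nt, n_trials_per_cond, config$pink_sd_uv) +
        matrix(stats::rnorm(nt * n_trials_per_cond, 0, config$white_sd_uv),
               nt, n_trials_per_cond)
      data[rows, 1, ] <- t(noise + sig)
    }
    epoch_array(data, fs, window[1], channels = "Cz",
                labels = labels, alignment = "itd_jump")
  })
}

#' Render a subject's alternating-polarity FFR epochs
#'
#' Probe-1 response: `polarity * (A_neural + A_preneural) * sin(2 pi 500 t)`
#' plus a polarity-invariant 1000-Hz rectification component with the same
#' neural/preneural split; probe-2 response identical except every neural
#' part is multiplied by `(1 - alpha)` (forward masking spares the
#' preneural, e.g. cochlear-microphonic, part). White sensor noise is added
#' per trial.
#'
#' @param subject one row of a [sample_cohort()] table.
#' @param n_trials total trials, even (polarity alternates).
#' @param seed integer seed.
#' @param config a [cohort_config()].
#' @param fs sampling rate (default 4000: an integer number of samples per
#'   500-Hz cycle, so the analysis bins land exactly on the components).
#' @param prestim_s pre-stimulus baseline included in the epoch.
#' @param rect_scale amplitude of the 1000-Hz rectification component
#'   relative to the 500-Hz component.
#' @return an [epoch_array()] with polarity labels (+1/-1), channel `Cz`.
#' @export
render_ffr <- function(subject, n_trials = 8000, seed = 1,
                       config = cohort_config(), fs = 4000,
                       prestim_s = 0.05, rect_scale = 0.5) {
  stopifnot(n_trials %% 2 == 0)
  local_seed(derive_seed(seed, subject$subject, 7002), {
    dur <- 0.351
    nt <- round((prestim_s + dur) * fs)
    t <- -prestim_s + (0:(nt - 1)) / fs
    An <- subject$ffr_A_neural; Ac <- subject$ffr_A_preneural
    alpha <- subject$ffr_alpha
    seg <- function(onset) t >= onset & t < onset + 0.1
    p1 <- seg(0); mk <- seg(0.15); p2 <- seg(0.251)
    tfs <- function(mask, amp, onset)
      amp * sin(2 * pi * 500 * (t - onset)) * mask
    rect <- function(mask, amp, onset)
      rect_scale * amp * sin(2 * pi * 1000 * (t - onset)) * mask
    # polarity-flipping 500-Hz part (neural + preneural mixture)
    flip <- tfs(p1, An + Ac, 0) + tfs(mk, 1.5 * (An + Ac), 0.15) +
      tfs(p2, (1 - alpha) * An + Ac, 0.251)
    # polarity-invariant 1000-Hz rectification part, same split
    inv <- rect(p1, An + Ac, 0) + rect(mk, 1.5 * (An + Ac), 0.15) +
      rect(p2, (1 - alpha) * An + Ac, 0.251)
    polarity <- rep(c(1, -1), n_trials / 2)
    data <- array(NA_real_, c(n_trials, 1, nt))
    base <- outer(polarity, flip) + matrix(inv, n_trials, nt, byrow = TRUE)
    if (config$ffr_noise_sd_uv > 0)
      base <- base + matrix(stats::rnorm(n_trials * nt, 0,
                                         config$ffr_noise_sd_uv),
                            n_trials, nt)
    data[, 1, ] <- base
    epoch_array(data, fs, -prestim_s, channels = "Cz",
                labels = polarity, alignment = "probe1_on")
  })
}
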