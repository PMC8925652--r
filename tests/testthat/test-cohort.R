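# Synthetic-cohort generators: determinism, latent structure, and the
# behavior/EEG/FFR forward models against their intended effects.

test_that("cohort sampling is reproducible and respects degenerate SDs", {
  cfg <- cohort_config()
  a <- sample_cohort(cfg, 42)
  b <- sample_cohort(cfg, 42)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(cfg, 43)))

  expect_identical(nrow(a), 32L)
  expect_true(all(c("subject", "theta_b", "theta_m", "lapse", "eeg_gain",
                    "eeg_latency_shift", "itd_mid_log", "itd_steep",
                    "ffr_A_neural", "ffr_A_preneural", "ffr_alpha")
                  %in% names(a)))

  cfg0 <- cohort_config(theta_b_sd = 0, theta_m_sd = 0, lapse_max = 0,
                        g_sdlog = 0, tau_coupling_s = 0, tau_noise_sd_s = 0,
                        itd_mid_coupling = 0, itd_mid_noise_sd = 0,
                        ffr_A_sdlog = 0)
  d <- sample_cohort(cfg0, 1)
  for (col in c("theta_b", "theta_m", "lapse", "eeg_gain",
                "eeg_latency_shift", "itd_mid_log", "ffr_A_neural"))
    expect_equal(diff(range(d[[col]])), 0)
  expect_equal(d$theta_b[1], cfg0$theta_b_mean)
})

test_that("rendered behavior recovers the sensory midpoint for ideal observers", {
  cfg <- cohort_config()
  subj <- make_subject(theta_b = 30, lapse = 0)
  runs <- render_behavior(subj, "itd", cfg, seed = 3)
  expect_length(runs, 8)
  s <- summarize_task_runs(runs)
  target <- 30 + 2 * qlogis((0.5^(1 / 3) - 0.5) / 0.5)
  expect_lt(abs(s$threshold_db - target), 2)
  runs2 <- render_behavior(subj, "itd", cfg, seed = 3)
  expect_identical(vapply(runs2, `[[`, numeric(1), "threshold"),
                   vapply(runs, `[[`, numeric(1), "threshold"))
})

test_that("lapsing raises rendered thresholds and shows in the catch score", {
  cfg <- cohort_config()
  th <- vapply(c(0, 0.2), function(lam) {
    mean(vapply(1:12, function(k) {
      subj <- make_subject(theta_b = 28, lapse = lam, id = k)
      summarize_task_runs(render_behavior(subj, "itd", cfg,
                                          seed = 100 + k))$threshold_db
    }, numeric(1)))
  }, numeric(1))
  expect_gt(th[2], th[1] + 1)

  # catch score is an unbiased lambda estimate (asymptote 1 - lambda)
  subj <- make_subject(theta_b = 26, lapse = 0.16)
  runs <- unlist(lapply(1:6, function(k)
    render_behavior(subj, "itd", cfg, seed = 500 + k)), recursive = FALSE)
  lr <- compute_lapse_rate(runs)
  p_expect <- 0.16
  se <- sqrt(p_expect * (1 - p_expect) / lr$n_catch)
  expect_lt(abs(lr$lapse_rate - p_expect), 4 * se + 0.01)
})

test_that("noiseless cortical epochs give ITC 1 where response energy exists", {
  cfg0 <- cohort_config(pink_sd_uv = 0, white_sd_uv = 0)
  subj <- make_subject()
  ep <- render_cortical_eeg(subj, conditions = 180, n_trials_per_cond = 5,
                            seed = 1, config = cfg0)
  m <- compute_itc(ep, freqs = c(5, 10, 41))
  expect_gt(min(m$values), 1 - 1e-6)
})

test_that("EEG gain boosts ITC scalars but post-hoc scaling cannot", {
  cfg <- cohort_config()
  scalar_for <- function(gain) {
    subj <- make_subject(gain = gain)
    ep <- render_cortical_eeg(subj, conditions = 540, n_trials_per_cond = 80,
                              seed = 5, config = cfg)
    lowband_itc_timecourse(compute_itc(ep, freqs = 1:20))$scalar
  }
  expect_gt(scalar_for(2), scalar_for(1))              # pre-noise gain: more SNR

  subj <- make_subject()
  ep <- render_cortical_eeg(subj, conditions = 540, n_trials_per_cond = 60,
                            seed = 6, config = cfg)
  m1 <- cortical_condition_metrics(ep, latency_condition = "540")
  ep$data <- ep$data * 3.7                             # anatomy-free rescale
  m2 <- cortical_condition_metrics(ep, latency_condition = "540")
  expect_equal(m1$itc_scalars, m2$itc_scalars, tolerance = 1e-12)
  expect_identical(m1$latency_s, m2$latency_s)
})

test_that("small ITD jumps evoke near-floor responses", {
  cfg <- cohort_config()
  subj <- make_subject()                               # a(20 us) ~ 0.08
  ep <- render_cortical_eeg(subj, conditions = c(20, 540),
                            n_trials_per_cond = 120, seed = 9, config = cfg)
  m <- cortical_condition_metrics(ep, latency_condition = "540")
  expect_lt(m$itc_scalars[["20"]], 0.3 * m$itc_scalars[["540"]])
})

test_that("condition ITC scalars grow monotonically with jump size", {
  cfg <- cohort_config()
  subj <- make_subject(gain = 1.3)
  ep <- render_cortical_eeg(subj, n_trials_per_cond = 150, seed = 11,
                            config = cfg)
  m <- cortical_condition_metrics(ep)
  expect_true(all(diff(m$itc_scalars[c("20", "60", "180", "540")]) > -0.01))
  expect_gt(m$itc_scalars[["540"]], m$itc_scalars[["20"]])
})
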