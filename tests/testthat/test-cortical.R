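# ITC, low-band time course, ASSR quality, N1/P2 peaks and the growth slope.

test_that("ITC of identical epochs is 1 and is amplitude-scale invariant", {
  fs <- 128
  t <- seq(-0.5, 0.7 - 1 / fs, by = 1 / fs)
  x <- matrix(rep(sin(2 * pi * 5 * t) + 0.3 * sin(2 * pi * 12 * t), 20),
              20, byrow = TRUE)
  ep <- make_epochs(x, fs, -0.5)
  m <- compute_itc(ep, freqs = c(3, 5, 12))
  expect_lt(max(abs(m$values - 1)), 1e-9)

  set.seed(5)
  xr <- matrix(rnorm(30 * length(t)), 30)
  epr <- make_epochs(xr, fs, -0.5)
  m1 <- compute_itc(epr, freqs = c(4, 10))
  eps <- make_epochs(xr * 57.3, fs, -0.5)
  m2 <- compute_itc(eps, freqs = c(4, 10))
  expect_equal(m1$values, m2$values, tolerance = 1e-12)  # phase-only statistic
  expect_true(all(m1$values >= 0 & m1$values <= 1))
  expect_error(compute_itc(make_epochs(xr[1, , drop = FALSE], fs, -0.5)),
               "at least 2")
})

test_that("ITC of uniform-phase epochs matches the resultant-length null", {
  # compact version (60 replicates); the 200-replicate run is in acceptance
  fs <- 128
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  set.seed(6)
  vals <- vapply(1:60, function(r) {
    ph <- runif(100, 0, 2 * pi)
    x <- t(vapply(ph, function(p) cos(2 * pi * 10 * t + p), numeric(length(t))))
    m <- compute_itc(make_epochs(x, fs, -0.5), freqs = 10)
    m$values[1, which.min(abs(m$times))]
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - sqrt(pi / 400)), 4 * se)
})

test_that("flat ITC maps give a zero condition scalar", {
  fake <- structure(list(values = matrix(0.37, 20, 50), freqs = 1:20,
                         times = seq(-0.45, 0.53, length.out = 50),
                         n_trials = 10), class = "itc_map")
  lb <- lowband_itc_timecourse(fake)
  expect_equal(lb$timecourse, rep(0.37, 50))
  expect_equal(lb$scalar, 0, tolerance = 1e-12)
  fake$freqs <- 1:10
  fake$values <- fake$values[1:10, ]
  expect_error(lowband_itc_timecourse(fake), "does not reach")
})

test_that("the jump scalar grows with response SNR", {
  fs <- 128
  t <- seq(-0.5, 0.7 - 1 / fs, by = 1 / fs)
  kernel <- -exp(-(t - 0.1)^2 / (2 * 0.025^2)) + exp(-(t - 0.2)^2 / (2 * 0.025^2))
  scalar_at <- function(amp, seed) {
    set.seed(seed)
    x <- matrix(rnorm(80 * length(t), 0, 4), 80, byrow = TRUE) +
      matrix(rep(amp * kernel, 80), 80, byrow = TRUE)
    m <- compute_itc(make_epochs(x, fs, -0.5), freqs = 1:20)
    lowband_itc_timecourse(m)$scalar
  }
  s <- vapply(c(0, 2, 6), scalar_at, numeric(1), seed = 7)
  expect_true(all(diff(s) > 0))
})

test_that("ASSR quality separates coherent 40.8-Hz activity from noise", {
  fs <- 256
  t <- seq(-0.5, 0.7 - 1 / fs, by = 1 / fs)
  set.seed(8)
  n_tr <- 60
  noise <- matrix(rnorm(n_tr * length(t), 0, 3), n_tr)
  coh <- noise + matrix(rep(sin(2 * pi * 40.8 * t), n_tr), n_tr, byrow = TRUE)
  q_coh <- assr_quality(make_epochs(coh, fs, -0.5), seed = 2)
  expect_true(q_coh$above_floor)
  q_noise <- assr_quality(make_epochs(noise, fs, -0.5), seed = 2)
  expect_false(q_noise$above_floor)
  off <- noise + matrix(rep(sin(2 * pi * 35 * t), n_tr), n_tr, byrow = TRUE)
  q_off <- assr_quality(make_epochs(off, fs, -0.5), seed = 2)
  expect_false(q_off$above_floor)                      # off-frequency control
})

test_that("N1/P2 detection recovers constructed peaks with equivariance", {
  fs <- 1000
  t <- seq(-0.2, 0.5 - 1 / fs, by = 1 / fs)
  g <- function(mu) exp(-(t - mu)^2 / (2 * 0.02^2))
  ev <- -g(0.10) + g(0.20)
  p <- detect_n1_p2(ev, t)
  expect_equal(p$n1_latency, 0.10, tolerance = 1e-9)
  expect_equal(p$p2_latency, 0.20, tolerance = 1e-9)
  expect_equal(p$latency_metric, 0.15, tolerance = 1e-9)
  expect_lt(p$n1_latency, p$p2_latency)

  ev_shift <- -g(0.13) + g(0.23)                       # +30 ms
  p2 <- detect_n1_p2(ev_shift, t)
  expect_equal(p2$latency_metric, p$latency_metric + 0.03, tolerance = 1e-9)

  p3 <- detect_n1_p2(ev * 10, t)                       # scale invariant
  expect_identical(p3$n1_latency, p$n1_latency)
  expect_identical(p3$p2_latency, p$p2_latency)
})

test_that("growth slope is the normalized 60-to-180 rise", {
  expect_equal(itd_growth_slope(c("60" = 0.1, "180" = 0.3, "540" = 0.5)), 0.4)
  expect_equal(itd_growth_slope(c("60" = 0.2, "180" = 0.2, "540" = 0.2)), 0)
  s1 <- itd_growth_slope(c("60" = 0.1, "180" = 0.3, "540" = 0.5))
  s2 <- itd_growth_slope(3 * c("60" = 0.1, "180" = 0.3, "540" = 0.5))
  expect_equal(s1, s2, tolerance = 1e-12)              # scale cancels
  expect_true(is.na(itd_growth_slope(c("60" = 0.1, "180" = 0.2, "540" = 0),
                                     noise_floor = 0)))
})
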