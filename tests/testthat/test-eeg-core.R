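# Preprocessing: re-referencing, zero-phase filtering, SSP, epoching.

make_rec <- function(data, rate, events = NULL) {
  eeg_recording(data, rate, events)
}

test_that("earlobe re-referencing removes common-mode signal", {
  set.seed(1)
  ch <- c("Fz", "Cz", "A1", "A2", "Fp1")
  x <- matrix(rnorm(5 * 100), 5, dimnames = list(ch, NULL))
  rec <- make_rec(x, 100)
  rr <- rereference_earlobes(rec)
  expect_equal(colMeans(rr$data[c("A1", "A2"), ]), rep(0, 100),
               tolerance = 1e-12)

  # identical earlobes: equivalent to subtracting either one
  x2 <- x; x2["A2", ] <- x2["A1", ]
  rr2 <- rereference_earlobes(make_rec(x2, 100))
  expect_equal(rr2$data["Fz", ], x2["Fz", ] - x2["A1", ], tolerance = 1e-12)

  # common offset on every channel is removed
  rr3 <- rereference_earlobes(make_rec(x + 42, 100))
  expect_equal(rr3$data, rr$data, tolerance = 1e-12)
  expect_error(rereference_earlobes(make_rec(x[1:2, ], 100)), "earlobe")
})

test_that("band-pass keeps the passband and rejects out-of-band energy", {
  fs <- 4000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- rbind(Fz = sin(2 * pi * 500 * t) + sin(2 * pi * 100 * t) + 5,
             Cz = sin(2 * pi * 500 * t))
  rec <- eeg_bandpass(make_rec(x, fs), 400, 1300)
  mid <- round(length(t) / 4):(3 * round(length(t) / 4))
  amp_at <- function(ch, f0) {
    sp <- amp_spectrum(rec$data[ch, mid], fs)
    sp$a[which.min(abs(sp$f - f0))]
  }
  expect_gt(amp_at("Cz", 500), 10^(-1 / 20))          # < 1 dB passband loss
  expect_lt(amp_at("Fz", 100), 10^(-40 / 20))         # >= 40 dB stopband
  expect_lt(abs(mean(rec$data["Fz", mid])), 1e-3)     # DC removed
  # zero phase: 500-Hz component unshifted on Cz
  ref <- sin(2 * pi * 500 * t[mid])
  expect_gt(cor(rec$data["Cz", mid], ref), 0.999)
})

test_that("low-frequency cortical band preserves a 10-Hz component", {
  fs <- 256
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- rbind(Cz = sin(2 * pi * 10 * t))
  rec <- eeg_bandpass(make_rec(x, fs), 1, 50)
  mid <- round(length(t) / 4):(3 * round(length(t) / 4))
  rms_ratio <- sqrt(mean(rec$data["Cz", mid]^2) / mean(x[1, mid]^2))
  expect_gt(rms_ratio, 10^(-1 / 20))
  expect_lt(rms_ratio, 10^(1 / 20))
})

test_that("preprocessing is linear in the recording", {
  set.seed(2)
  fs <- 4000
  a <- matrix(rnorm(2 * fs), 2, dimnames = list(c("Fz", "Cz"), NULL))
  b <- matrix(rnorm(2 * fs), 2, dimnames = list(c("Fz", "Cz"), NULL))
  fa <- eeg_bandpass(make_rec(a, fs), 400, 1300)$data
  fb <- eeg_bandpass(make_rec(b, fs), 400, 1300)$data
  fab <- eeg_bandpass(make_rec(a + b, fs), 400, 1300)$data
  expect_equal(fab, fa + fb, tolerance = 1e-8)
})

test_that("SSP removes a rank-1 blink while sparing orthogonal activity", {
  set.seed(3)
  fs <- 256; n <- fs * 30; nch <- 6
  ch <- c("Fp1", "Fz", "Cz", "Pz", "A1", "A2")
  blink_topo <- c(1, 0.6, 0.3, 0.1, 0.05, 0.05)
  neural_topo <- c(0, -0.3, 0.8, 0.5, 0, 0)
  neural_topo <- neural_topo - blink_topo *
    sum(neural_topo * blink_topo) / sum(blink_topo^2)   # orthogonalize
  blink_tc <- numeric(n)
  for (s in seq(2 * fs, n - fs, by = 3 * fs))           # ~120-ms blinks
    blink_tc[s:(s + 30)] <- 200 * exp(-((0:30) - 15)^2 / 50)
  neural_tc <- 5 * sin(2 * pi * 7 * (1:n) / fs)
  x <- outer(blink_topo, blink_tc) + outer(neural_topo, neural_tc) +
    matrix(rnorm(nch * n, 0, 0.5), nch)
  rownames(x) <- ch
  out <- remove_blinks_ssp(make_rec(x, fs), frontal = "Fp1")
  P <- out$projector
  expect_equal(P %*% P, P, tolerance = 1e-10)          # idempotent
  expect_equal(P, t(P), tolerance = 1e-10)

  blink_part <- function(d) as.numeric(blink_topo %*% d) / sum(blink_topo^2)
  expect_lt(var(blink_part(out$recording$data)) / var(blink_part(x)), 0.10)
  neural_part <- function(d) as.numeric(neural_topo %*% d) / sum(neural_topo^2)
  expect_gt(var(neural_part(out$recording$data)) / var(neural_part(x)), 0.95)

  ident <- remove_blinks_ssp(make_rec(x, fs), frontal = "Fp1",
                             n_projectors = 0)
  expect_equal(ident$recording$data, x)
  quiet <- matrix(rnorm(nch * fs, 0, 0.1), nch, dimnames = list(ch, NULL))
  expect_warning(remove_blinks_ssp(make_rec(quiet, fs), frontal = "Fp1"),
                 "no blink")
})

test_that("epoch rejection masks exactly the over-threshold epochs", {
  fs <- 100
  n <- fs * 12
  x <- matrix(rnorm(2 * n, 0, 5), 2, dimnames = list(c("Fz", "Cz"), NULL))
  ev <- data.frame(sample = seq(fs, n - fs, by = fs), code = "stim")
  x["Cz", ev$sample[4] + 10] <- 200                    # one bad epoch
  rec <- make_rec(x, fs, ev)
  ep150 <- epoch_and_reject(rec, "stim", -0.2, 0.5, 150)
  expect_identical(which(ep150$rejected), 4L)
  ep50 <- epoch_and_reject(rec, "stim", -0.2, 0.5, 50)
  expect_true(all(which(ep150$rejected) %in% which(ep50$rejected)))
  expect_gte(sum(ep50$rejected), sum(ep150$rejected)) # monotone in threshold

  quiet <- make_rec(matrix(rnorm(2 * n, 0, 1), 2,
                           dimnames = list(c("Fz", "Cz"), NULL)), fs, ev)
  expect_identical(sum(epoch_and_reject(quiet, "stim", -0.2, 0.5,
                                        150)$rejected), 0L)
})

test_that("epoch averaging commutes with re-referencing", {
  set.seed(4)
  fs <- 100; n <- fs * 10
  ch <- c("Fz", "Cz", "A1", "A2")
  x <- matrix(rnorm(4 * n), 4, dimnames = list(ch, NULL))
  ev <- data.frame(sample = seq(fs, n - fs, by = fs), code = "s")
  rec <- make_rec(x, fs, ev)
  a <- evoked_average(epoch_and_reject(rereference_earlobes(rec), "s",
                                       -0.1, 0.3, 1e6), "Cz")
  ep <- epoch_and_reject(rec, "s", -0.1, 0.3, 1e6)
  ref_avg <- (evoked_average(ep, "A1") + evoked_average(ep, "A2")) / 2
  b <- evoked_average(ep, "Cz") - ref_avg
  expect_equal(a, b, tolerance = 1e-12)
})
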