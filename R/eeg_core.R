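# EEG preprocessing: earlobe re-referencing, zero-phase band-pass filtering,
# blink removal by signal-space projection, epoching and amplitude rejection.

#' Continuous multichannel EEG recording
#'
#' @param data channels x samples matrix (uV) with unique rownames.
#' @param rate sampling rate, samples/s.
#' @param events data.frame with columns `sample` (1-based index) and `code`;
#'   an optional `label` column carries per-event condition labels.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, events = NULL) {
  stopifnot(is.matrix(data), !is.null(rownames(data)),
            !anyDuplicated(rownames(data)), rate > 0)
  if (is.null(events))
    events <- data.frame(sample = integer(0), code = character(0))
  stopifnot(all(c("sample", "code") %in% names(events)))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample outside the recording")
  structure(list(data = data, rate = rate, events = events),
            class = "eeg_recording")
}

#' Re-reference a recording to the average of the two earlobe channels
#' @param rec an [eeg_recording()].
#' @param earlobes names of the two earlobe channels.
#' @return the re-referenced recording.
#' @export
rereference_earlobes <- function(rec, earlobes = c("A1", "A2")) {
  missing_ch <- setdiff(earlobes, rownames(rec$data))
  if (length(missing_ch))
    stop("missing earlobe channel(s): ", paste(missing_ch, collapse = ", "))
  ref <- colMeans(rec$data[earlobes, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref, "-")
  rec
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) FIR designed for ~40 dB stopband attenuation one
#' octave outside the band, applied forward-backward (`signal::filtfilt`) so
#' the net phase response is zero and latency metrics are undistorted.
#'
#' @param rec an [eeg_recording()].
#' @param lo_hz,hi_hz band edges, `0 < lo < hi < rate/2`.
#' @param max_order cap on the FIR order (guards short recordings).
#' @return the filtered recording.
#' @export
eeg_bandpass <- function(rec, lo_hz, hi_hz, max_order = NULL) {
  fs <- rec$rate
  stopifnot(lo_hz > 0, hi_hz > lo_hz, hi_hz < fs / 2)
  trans <- lo_hz / 2               # reach the stopband one octave below lo
  n <- ceiling(3.3 * fs / trans)   # Hamming transition-width rule
  n <- n + n %% 2                  # even order -> odd symmetric taps
  limit <- floor((ncol(rec$data) - 1) / 3)
  if (!is.null(max_order)) limit <- min(limit, max_order)
  if (n > limit) {
    n <- limit - limit %% 2
    warning("recording short for the requested low edge; FIR order capped at ", n)
  }
  taps <- signal::fir1(n, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  nm <- rownames(rec$data)
  filtered <- t(apply(rec$data, 1, function(x)
    signal::filtfilt(taps, x)))   # taps is an "Ma" object; a = 1 implied
  rownames(filtered) <- nm
  rec$data <- filtered
  rec
}

#' Remove blink artifacts by signal-space projection
#'
#' Blink exemplars are detected as runs where the frontal channel exceeds
#' `thresh_sd` robust SDs for at least `min_dur_s`; the leading spatial
#' principal components of those segments define an orthogonal projection
#' `P = I - U U'` that is applied to every sample.
#'
#' @param rec an [eeg_recording()].
#' @param frontal name of the frontal/EOG-proxy channel used for detection.
#' @param n_projectors number of spatial components to project out (0 =
#'   identity).
#' @param thresh_sd detection threshold in robust (MAD-based) SDs.
#' @param min_dur_s minimum excursion duration counted as a blink.
#' @return list with `recording` (cleaned) and `projector` (channels x
#'   channels matrix, idempotent and symmetric).
#' @export
remove_blinks_ssp <- function(rec, frontal = "Fp1", n_projectors = 1,
                              thresh_sd = 4, min_dur_s = 0.05) {
  nch <- nrow(rec$data)
  if (n_projectors == 0)
    return(list(recording = rec, projector = diag(nch)))
  stopifnot(frontal %in% rownames(rec$data))
  x <- rec$data[frontal, ]
  dev <- abs(x - stats::median(x))
  sdr <- stats::mad(x)
  above <- dev > thresh_sd * sdr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= round(min_dur_s * rec$rate)
  if (!any(keep)) {
    warning("no blink exemplars found: returning identity projection")
    return(list(recording = rec, projector = diag(nch)))
  }
  idx <- unlist(mapply(seq, starts[keep], ends[keep], SIMPLIFY = FALSE))
  seg <- rec$data[, idx, drop = FALSE]
  seg <- seg - rowMeans(seg)
  sv <- svd(seg, nu = n_projectors, nv = 0)
  U <- sv$u
  P <- diag(nch) - U %*% t(U)
  out <- rec
  out$data <- P %*% rec$data
  rownames(out$data) <- rownames(rec$data)
  list(recording = out, projector = P)
}

#' Epoch tensor aligned to a named event
#'
#' @param data trials x channels x time array (uV).
#' @param rate sampling rate.
#' @param tmin epoch start relative to the alignment event (s, <= 0).
#' @param channels channel names (length = dim 2).
#' @param labels per-trial condition labels (length = dim 1) or NULL.
#' @param rejected logical rejection mask (TRUE = excluded) or NULL.
#' @param alignment code of the alignment event.
#' @return an object of class `epoch_array`; `$times` gives the time axis
#'   relative to the event.
#' @export
epoch_array <- function(data, rate, tmin, channels, labels = NULL,
                        rejected = NULL, alignment = NULL) {
  stopifnot(length(dim(data)) == 3, length(channels) == dim(data)[2])
  n_trials <- dim(data)[1]; n_time <- dim(data)[3]
  times <- tmin + (0:(n_time - 1)) / rate
  if (!(times[1] <= 0 && times[n_time] >= 0))
    stop("epoch window must contain t = 0")
  if (is.null(rejected)) rejected <- rep(FALSE, n_trials)
  stopifnot(length(rejected) == n_trials)
  if (!is.null(labels)) stopifnot(length(labels) == n_trials)
  structure(list(data = data, rate = rate, tmin = tmin, times = times,
                 channels = channels, labels = labels, rejected = rejected,
                 alignment = alignment, schema = "tfsassay-epochs-1"),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("<epoch_array> %d trials (%d rejected) x %d ch x %d samples @ %g Hz, window [%.3f, %.3f] s\n",
              dim(x$data)[1], sum(x$rejected), dim(x$data)[2],
              dim(x$data)[3], x$rate, x$times[1], utils::tail(x$times, 1)))
  invisible(x)
}

#' Indices of trials surviving rejection
#' @param epochs an [epoch_array()].
#' @export
good_trials <- function(epochs) which(!epochs$rejected)

#' Cut epochs around events and reject large voltage excursions
#'
#' One epoch per event carrying `code`; an epoch is masked when the absolute
#' amplitude on any analysis channel exceeds `reject_uv` anywhere in the
#' window. Masked epochs are excluded from all downstream averages.
#'
#' @param rec an [eeg_recording()].
#' @param code event code to align on.
#' @param tmin,tmax window relative to the event (s).
#' @param reject_uv rejection threshold (uV, > 0); 150 for cortical and 50
#'   for subcortical analyses by convention.
#' @param channels analysis channels used for rejection (default Fz, Cz).
#' @return an [epoch_array()] over all channels, with the rejection mask set.
#' @export
epoch_and_reject <- function(rec, code, tmin, tmax, reject_uv,
                             channels = c("Fz", "Cz")) {
  stopifnot(reject_uv > 0, tmin < 0, tmax > 0)
  ev <- rec$events[rec$events$code == code, , drop = FALSE]
  if (!nrow(ev)) stop("no events with code '", code, "'")
  n0 <- round(tmin * rec$rate); n1 <- round(tmax * rec$rate)
  ok <- ev$sample + n0 >= 1 & ev$sample + n1 <= ncol(rec$data)
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) stop("no events with a complete epoch window")
  nch <- nrow(rec$data); nt <- n1 - n0 + 1
  data <- array(NA_real_, c(nrow(ev), nch, nt))
  for (i in seq_len(nrow(ev)))
    data[i, , ] <- rec$data[, (ev$sample[i] + n0):(ev$sample[i] + n1)]
  chsel <- intersect(channels, rownames(rec$data))
  if (!length(chsel)) stop("no analysis channel present for rejection")
  ci <- match(chsel, rownames(rec$data))
  rejected <- apply(data[, ci, , drop = FALSE], 1,
                    function(m) max(abs(m)) > reject_uv)
  if (all(rejected)) stop("all epochs rejected at ", reject_uv, " uV")
  labels <- if ("label" %in% names(ev)) ev$label else NULL
  epoch_array(data, rec$rate, n0 / rec$rate, rownames(rec$data),
              labels = labels, rejected = rejected, alignment = code)
}

#' Average evoked response on one channel over surviving trials
#' @param epochs an [epoch_array()].
#' @param channel channel name.
#' @param trials optional trial indices (defaults to all surviving trials).
#' @return numeric vector over `epochs$times`.
#' @export
evoked_average <- function(epochs, channel = "Cz", trials = NULL) {
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stop("channel '", channel, "' not found")
  if (is.null(trials)) trials <- good_trials(epochs)
  if (!length(trials)) stop("no surviving trials")
  m <- matrix(epochs$data[trials, ci, ], nrow = length(trials))
  colMeans(m)
}
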