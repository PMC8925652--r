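#' Stereo waveform container
#'
#' A calibrated two-channel audio signal carrying one stimulus paradigm
#' instance. Samples are dimensionless full-scale values in \[-1, 1\]; the
#' `calibration` field records the sound pressure level (dB SPL) that a
#' full-scale sinusoid would produce, so physical levels are recoverable.
#'
#' @param left,right numeric sample vectors (equal length, |x| <= 1).
#' @param rate sampling rate in samples/s.
#' @param calibration_db_spl dB SPL produced by a full-scale sinusoid.
#' @param events data.frame with columns `time` (s) and `label`, or NULL.
#' @param paradigm character tag for the paradigm that produced the waveform.
#' @param params list of paradigm parameters (stored for provenance).
#' @return an object of class `stereo_waveform`.
#' @export
stereo_waveform <- function(left, right, rate, calibration_db_spl = 100,
                            events = NULL, paradigm = NULL, params = list()) {
  stopifnot(is.numeric(left), is.numeric(right), length(left) == length(right),
            is.numeric(rate), length(rate) == 1L, rate > 0)
  peak <- max(abs(c(left, right)), 0)
  if (peak > 1 + 1e-9)
    stop("waveform clips: max |sample| = ", signif(peak, 4), " > 1")
  dur <- length(left) / rate
  if (is.null(events))
    events <- data.frame(time = numeric(0), label = character(0),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("time", "label") %in% names(events)))
  if (nrow(events) && (any(events$time < -1e-12) | any(events$time > dur + 1e-12)))
    stop("event time outside [0, duration]")
  structure(list(left = left, right = right, rate = rate,
                 calibration_db_spl = calibration_db_spl,
                 events = events, paradigm = paradigm, params = params),
            class = "stereo_waveform")
}

#' @export
print.stereo_waveform <- function(x, ...) {
  cat(sprintf("<stereo_waveform> %s: %.3f s @ %g Hz, cal %.1f dB SPL, %d events\n",
              if (is.null(x$paradigm)) "?" else x$paradigm,
              length(x$left) / x$rate, x$rate, x$calibration_db_spl,
              nrow(x$events)))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wf a `stereo_waveform`.
#' @export
wf_duration <- function(wf) length(wf$left) / wf$rate

#' Convert a presentation level to a linear full-scale amplitude
#'
#' Given the calibration convention that a full-scale sinusoid produces
#' `calibration` dB SPL, a tone at `level_db_spl` needs peak amplitude
#' `10^((level - calibration)/20)`.
#'
#' @param level_db_spl desired presentation level, dB SPL.
#' @param calibration dB SPL of a full-scale sinusoid (> 0).
#' @return linear peak amplitude in (0, 1].
#' @export
db_spl_to_amplitude <- function(level_db_spl, calibration = 100) {
  stopifnot(calibration > 0)
  if (any(level_db_spl > calibration))
    stop("requested level exceeds calibration: output would clip")
  10^((level_db_spl - calibration) / 20)
}

#' Write a stereo waveform to a 16-bit PCM WAV file with a JSON sidecar
#'
#' Minimal RIFF/WAVE writer (artifact plumbing). The sidecar records the
#' paradigm, parameters, calibration and event list so the physical stimulus
#' is fully reproducible from the file pair.
#'
#' @param wf a `stereo_waveform`.
#' @param path output `.wav` path; the sidecar is written to `<path>.json`.
#' @param sidecar write the JSON sidecar? (default TRUE)
#' @return `path`, invisibly.
#' @export
write_wav <- function(wf, path, sidecar = TRUE) {
  n <- length(wf$left)
  pcm <- as.integer(round(pmax(-1, pmin(1, rbind(wf$left, wf$right))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(2L, con, size = 2, endian = "little")            # stereo
  writeBin(as.integer(wf$rate), con, size = 4, endian = "little")
  writeBin(as.integer(wf$rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.vector(pcm), con, size = 2, endian = "little")
  if (sidecar) {
    meta <- list(paradigm = wf$paradigm, parameters = wf$params,
                 calibration_db_spl = wf$calibration_db_spl,
                 rate = wf$rate,
                 events = wf$events)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read back a 16-bit PCM stereo WAV written by [write_wav()]
#' @param path `.wav` path.
#' @return list with `left`, `right`, `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  readChar(con, 8)                                          # WAVEfmt
  fmt_len <- readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 2, endian = "little")      # PCM tag
  n_ch <- readBin(con, integer(), size = 2, endian = "little")
  rate <- readBin(con, integer(), size = 4, endian = "little")
  readBin(con, raw(), n = fmt_len - 8L)
  readChar(con, 4)                                          # "data"
  data_bytes <- readBin(con, integer(), size = 4, endian = "little")
  pcm <- readBin(con, integer(), n = data_bytes / 2L, size = 2,
                 signed = TRUE, endian = "little")
  x <- matrix(pcm / 32767, nrow = n_ch)
  list(left = x[1, ], right = x[min(2L, n_ch), ], rate = rate)
}

#' Export a waveform's event annotations as TSV (onset_s, code)
#' @param wf a `stereo_waveform`.
#' @param path output path.
#' @export
write_events_tsv <- function(wf, path) {
  ev <- wf$events
  names(ev) <- c("onset_s", "code")
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
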