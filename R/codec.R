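# Audio I/O and the spike-domain codec. The project-wide bipolar convention:
# a PDM bit density of 0.5 encodes zero amplitude, density (x+1)/2 encodes
# amplitude x in [-1, 1].

#' Binary spike train at the pulse clock
#'
#' @param bits Vector of 0/1 pulse bits.
#' @param clock_hz Pulse clock rate in Hz (positive).
#' @param encoding `"bipolar_midpoint"` (density 0.5 encodes zero) or
#'   `"unipolar"` (density encodes a non-negative rate).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(bits, clock_hz,
                        encoding = c("bipolar_midpoint", "unipolar")) {
  encoding <- match.arg(encoding)
  if (length(clock_hz) != 1 || !is.finite(clock_hz) || clock_hz <= 0)
    stop("`clock_hz` must be positive", call. = FALSE)
  bits <- as.integer(bits)
  if (any(is.na(bits)) || any(bits < 0L | bits > 1L))
    stop("`bits` must be 0/1", call. = FALSE)
  structure(list(bits = bits, clock_hz = clock_hz, encoding = encoding),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d ticks @ %g Hz (%s), density %.4f\n",
              length(x$bits), x$clock_hz, x$encoding, mean(x$bits)))
  invisible(x)
}

#' Mean pulse density of a spike train
#' @param train A [spike_train()].
#' @return Fraction of ticks carrying a pulse, in `[0, 1]`.
#' @export
spike_density <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  mean(train$bits)
}

#' Sampled mono waveform
#'
#' @param samples Amplitudes in `[-1, 1]`.
#' @param rate_hz Sample rate in Hz.
#' @param normalize Rescale to peak 1 when the input exceeds the range.
#' @return Object of class `waveform`.
#' @export
waveform <- function(samples, rate_hz, normalize = FALSE) {
  if (length(rate_hz) != 1 || !is.finite(rate_hz) || rate_hz <= 0)
    stop("`rate_hz` must be positive", call. = FALSE)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  peak <- max(abs(samples), 0)
  if (peak > 1) {
    if (!normalize)
      stop("samples exceed [-1, 1]; use normalize = TRUE", call. = FALSE)
    samples <- samples / peak
  }
  structure(list(samples = samples, rate_hz = rate_hz), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
              max(abs(x$samples))))
  invisible(x)
}

wave_duration <- function(wave) length(wave$samples) / wave$rate_hz

#' Pure sine waveform
#' @param freq_hz Tone frequency (below Nyquist).
#' @param duration_s Duration in seconds.
#' @param rate_hz Sample rate.
#' @param amplitude Peak amplitude in `(0, 1]`.
#' @param phase Initial phase in radians.
#' @export
sine_wave <- function(freq_hz, duration_s, rate_hz, amplitude = 1,
                      phase = 0) {
  if (freq_hz < 0 || freq_hz >= rate_hz / 2)
    stop("`freq_hz` must lie in [0, rate_hz/2)", call. = FALSE)
  t <- seq(0, duration_s, by = 1 / rate_hz)
  t <- t[-length(t)]
  waveform(amplitude * sin(2 * pi * freq_hz * t + phase), rate_hz)
}

#' Linear chirp waveform
#'
#' Unit-amplitude sweep with instantaneous frequency moving linearly from
#' `f_start` to `f_end` over the duration.
#'
#' @param f_start,f_end Sweep endpoints in Hz (below Nyquist).
#' @param duration_s Duration in seconds.
#' @param rate_hz Sample rate.
#' @param amplitude Peak amplitude.
#' @export
chirp_wave <- function(f_start, f_end, duration_s, rate_hz, amplitude = 1) {
  if (f_start < 0 || f_end < 0 || max(f_start, f_end) >= rate_hz / 2)
    stop("chirp frequencies must lie in [0, rate_hz/2)", call. = FALSE)
  t <- seq(0, duration_s, by = 1 / rate_hz)
  t <- t[-length(t)]
  k <- (f_end - f_start) / duration_s
  ph <- 2 * pi * (f_start * t + k * t^2 / 2)
  waveform(amplitude * sin(ph), rate_hz)
}

#' Read a mono 16-bit PCM WAV file
#' @param path Path to the file.
#' @return A [waveform()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little") # byte rate
      readBin(con, "integer", 1, 2, endian = "little") # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  if (bits != 16 || channels != 1)
    stop("only mono 16-bit PCM WAV is supported", call. = FALSE)
  waveform(samples / 32768, rate)
}

#' Write a mono 16-bit PCM WAV file
#' @param wave A [waveform()].
#' @param path Output path.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "waveform"))
  pcm <- as.integer(pmin(round(pmin(pmax(wave$samples, -1), 1) * 32768),
                         32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(wave$rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(wave$rate_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' PDM-encode a waveform (first-order sigma-delta)
#'
#' Deterministic one-bit encoding at the pulse clock: over any long window
#' the pulse density approximates `(mean(x) + 1) / 2`.
#'
#' @param wave A [waveform()].
#' @param clock_hz Pulse clock; must be at least twice the sample rate.
#' @return A bipolar [spike_train()].
#' @export
pdm_encode <- function(wave, clock_hz = 1.536e6) {
  stopifnot(inherits(wave, "waveform"))
  if (clock_hz < 2 * wave$rate_hz)
    stop("`clock_hz` must be >= 2x the waveform sample rate", call. = FALSE)
  bits <- pdm_encode_cpp(wave$samples, wave$rate_hz, clock_hz)
  spike_train(bits, clock_hz, encoding = "bipolar_midpoint")
}

fir_lowpass_taps <- function(clock_hz, cutoff_hz, order = NULL) {
  if (is.null(order)) {
    order <- min(8192L, max(32L, as.integer(round(4 * clock_hz / cutoff_hz))))
  }
  if (order %% 2L == 1L) order <- order + 1L # even order -> odd, symmetric taps
  taps <- signal::fir1(order, cutoff_hz / (clock_hz / 2), type = "low")
  taps / sum(taps)
}

#' Decode a PDM spike train back to a waveform
#'
#' Linear-phase windowed-sinc FIR low-pass with decimation; taps are centred
#' on each output sample so the decoder itself adds no phase shift.
#'
#' @param train A bipolar [spike_train()].
#' @param cutoff_hz Low-pass cutoff (below half the pulse clock).
#' @param out_rate_hz Output sample rate.
#' @param fir_order Optional FIR order (default scales with
#'   `clock_hz / cutoff_hz`, capped at 8192).
#' @return A [waveform()] at `out_rate_hz`, rescaled to `[-1, 1]`.
#' @export
pdm_decode <- function(train, cutoff_hz, out_rate_hz, fir_order = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (cutoff_hz <= 0 || cutoff_hz >= train$clock_hz / 2)
    stop("`cutoff_hz` must lie in (0, clock_hz/2)", call. = FALSE)
  taps <- fir_lowpass_taps(train$clock_hz, cutoff_hz, fir_order)
  y <- fir_decimate_cpp(train$bits, taps, train$clock_hz, out_rate_hz)
  waveform(pmin(pmax(y, -1), 1), out_rate_hz)
}

#' Persist a spike train as a packed bitstream
#'
#' Bits are packed eight per byte (little-endian within the byte) into
#' `path`; a small JSON sidecar `<path>.json` records the clock, the
#' encoding convention, and the exact bit length.
#'
#' @param train A [spike_train()].
#' @param path Destination for the packed bits.
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  n <- length(train$bits)
  pad <- (8 - n %% 8) %% 8
  bits <- c(train$bits, integer(pad))
  bytes <- as.raw(colSums(matrix(bits, nrow = 8) * 2^(0:7)))
  writeBin(bytes, path)
  jsonlite::write_json(
    list(clock_hz = train$clock_hz, encoding = train$encoding,
         n_bits = n),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spike train written by [write_spike_train()]
#' @param path Path to the packed bitstream (its `.json` sidecar must sit
#'   next to it).
#' @return The restored [spike_train()], bit for bit.
#' @export
read_spike_train <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bytes <- readBin(path, "raw", file.size(path))
  bits <- as.integer(rawToBits(bytes))[seq_len(hdr$n_bits)]
  spike_train(bits, hdr$clock_hz, hdr$encoding)
}

#' Binned spike rate of a train
#'
#' @param train A [spike_train()].
#' @param window_s Bin width in seconds (at least one tick).
#' @return Data frame with bin mid-times (`time_s`) and rates (`rate_hz`).
#' @export
spike_rate <- function(train, window_s) {
  stopifnot(inherits(train, "spike_train"))
  ticks <- max(1L, as.integer(round(window_s * train$clock_hz)))
  if (window_s * train$clock_hz < 1)
    stop("`window_s` must span at least one tick", call. = FALSE)
  n <- length(train$bits)
  idx <- (seq_len(n) - 1L) %/% ticks
  counts <- tapply(train$bits, idx, sum)
  nb <- length(counts)
  data.frame(time_s = ((seq_len(nb) - 0.5) * ticks) / train$clock_hz,
             rate_hz = as.numeric(counts) / (ticks / train$clock_hz))
}

#' Relative phase of one waveform against another at a probe frequency
#'
#' Cross-spectrum estimate with a Hann window: the returned value is the
#' phase of `signal` minus the phase of `reference` at `probe_hz`, in
#' degrees on `(-180, 180]`. A pure delay of a quarter period reads -90.
#'
#' @param reference,signal Two [waveform()]s at the same sample rate.
#' @param probe_hz Probe frequency (below Nyquist).
#' @param min_amplitude Error out when either windowed amplitude at the
#'   probe falls below this floor.
#' @return Phase in degrees.
#' @export
estimate_phase <- function(reference, signal, probe_hz,
                           min_amplitude = 1e-3) {
  stopifnot(inherits(reference, "waveform"), inherits(signal, "waveform"))
  if (reference$rate_hz != signal$rate_hz)
    stop("waveforms must share a sample rate", call. = FALSE)
  n <- min(length(reference$samples), length(signal$samples))
  if (probe_hz <= 0 || probe_hz >= reference$rate_hz / 2)
    stop("`probe_hz` must lie in (0, rate/2)", call. = FALSE)
  t <- (seq_len(n) - 1) / reference$rate_hz
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  osc <- exp(-2i * pi * probe_hz * t) * w
  x <- sum(reference$samples[seq_len(n)] * osc)
  y <- sum(signal$samples[seq_len(n)] * osc)
  amp <- 2 / sum(w)
  if (abs(x) * amp < min_amplitude || abs(y) * amp < min_amplitude)
    stop("probe power below the noise floor", call. = FALSE)
  ph <- Arg(y * Conj(x)) * 180 / pi
  if (ph <= -180) ph <- ph + 360
  ph
}
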