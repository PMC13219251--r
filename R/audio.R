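#' Audio rendering specification
#'
#' @param syllable_duration_ms Duration of every syllable (default 300).
#' @param target_level_db Nominal common level in dB (digital full-scale
#'   referenced: 85 dB corresponds to RMS 1.0); playback calibration is
#'   the experimenter's responsibility.
#' @param sample_rate Sampling rate in Hz (>= 8000, default 44100).
#' @return An `audio_spec`.
#' @export
audio_spec <- function(syllable_duration_ms = 300, target_level_db = 65,
                       sample_rate = 44100) {
  if (syllable_duration_ms <= 0) stop_ss("syllable_duration_ms must be > 0")
  if (sample_rate < 8000) stop_ss("sample_rate must be >= 8000")
  structure(list(syllable_duration_ms = syllable_duration_ms,
                 target_level_db = target_level_db,
                 sample_rate = sample_rate),
            class = "audio_spec")
}

spec_rms <- function(spec) 10^((spec$target_level_db - 85) / 20)

str_hash <- function(s) {
  v <- utf8ToInt(s)
  as.integer(sum(v * (seq_along(v) * 131L + 7L)) %% 1048573L)
}

cos_ramp <- function(x, sr, ms = 10) {
  n <- min(length(x) %/% 2L, round(sr * ms / 1000))
  if (n < 1) return(x)
  r <- 0.5 * (1 - cos(pi * seq_len(n) / n))
  x[seq_len(n)] <- x[seq_len(n)] * r
  x[(length(x) - n + 1L):length(x)] <-
    x[(length(x) - n + 1L):length(x)] * rev(r)
  x
}

# Deterministic harmonic-plus-noise synthesis of one syllable.  The
# consonant portion (duration, timbre) and the vowel harmonic amplitudes
# are derived from a hash of the syllable id, so every syllable has a
# distinctive amplitude envelope and spectrum.  Makes no naturalness
# claims: it exists so that modulation spectra and pitch contours are
# testable without recordings.
synth_syllable <- function(id, n, sr, f0_track = NULL, manner = NULL) {
  h <- str_hash(id)
  u <- function(k) ((h * (k * 2654435761) ) %% 1000003L) / 1000003
  manner <- manner %||% c("plosive", "fricative", "sonorant")[1 + h %% 3L]
  # consonant length is a manner signature (plus small per-syllable
  # jitter): words built under OCP-manner then have near-equal mean
  # envelopes, as duration/amplitude-equalized natural syllables do
  cons_frac <- switch(manner, plosive = 0.22, fricative = 0.38,
                      sonorant = 0.30) + 0.04 * (u(1) - 0.5)
  nc <- round(n * cons_frac)
  nv <- n - nc
  f0 <- if (is.null(f0_track)) 110 + 60 * u(2) else
    approx(seq(0, 1, length.out = length(f0_track)), f0_track,
           xout = seq(0, 1, length.out = n))$y
  f0v <- if (is.null(f0_track)) rep(f0, n) else f0
  ph <- 2 * pi * cumsum(f0v) / sr
  # vowel: four harmonics with hash-dependent (formant-like) weights
  amps <- c(1, 0.3 + 0.6 * u(3), 0.2 + 0.5 * u(4), 0.1 + 0.3 * u(5))
  vow <- amps[1] * sin(ph) + amps[2] * sin(2 * ph) +
    amps[3] * sin(3 * ph) + amps[4] * sin(4 * ph)
  noise <- withr::with_seed(h, stats::runif(nc, -1, 1))
  cons <- switch(manner,
    plosive = {  # closure silence then a short burst
      x <- numeric(nc)
      burst <- max(1L, round(nc * 0.4))
      x[(nc - burst + 1L):nc] <- noise[seq_len(burst)] * 0.8
      x
    },
    fricative = noise * 0.5,
    sonorant = 0.5 * sin(ph[seq_len(nc)]) * (1 + 0.2 * noise))
  env_c <- rep(0.35, nc)
  env_v <- 1 - 0.35 * (seq_len(nv) / nv)     # vowel decays
  x <- c(cons * env_c, vow[nc + seq_len(nv)] * env_v)
  cos_ramp(x, sr)
}

normalize_rms <- function(x, target) {
  r <- sqrt(mean(x^2))
  if (r == 0) stop_ss("zero-energy syllable waveform; cannot normalize RMS")
  x * (target / r)
}

syllable_manner <- function(stream, id) {
  for (w in stream$lexicon$words) {
    for (s in w$syllables) {
      if (s$id == id) {
        fm <- s$feature_matrix
        cslot <- which(strsplit(s$pattern, "")[[1]] == "c")[1]
        if (is.na(cslot)) return(NULL)
        g <- function(f) f %in% rownames(fm) && fm[f, cslot]
        return(if (g("son")) "sonorant"
               else if (g("cont")) "fricative" else "plosive")
      }
    }
  }
  NULL
}

#' Render a stream as an isochronous waveform
#'
#' Each syllable occupies exactly `syllable_duration_ms`; all syllables
#' are scaled to a common RMS.  Syllables are synthesized internally
#' (deterministic harmonic-plus-noise timbres) unless per-syllable
#' waveforms are supplied, in which case provided audio within 20% of
#' the target duration is uniformly time-scaled and otherwise padded or
#' truncated with 10-ms cosine ramps.
#'
#' @param stream A `stream`.
#' @param spec An [audio_spec()].
#' @param syllable_audio Optional named list/vector mapping syllable id to
#'   a mono WAV file path or numeric waveform at `spec$sample_rate`.
#' @param pitch_tracks Optional per-position pitch tracks from
#'   [apply_pitch_contour()] (drives the synthesis fundamental).
#' @return Numeric waveform with attributes `sample_rate` and
#'   `syllable_samples`; duration is exactly T x syllable_duration.
#' @export
render_stream_audio <- function(stream, spec = audio_spec(),
                                syllable_audio = NULL,
                                pitch_tracks = NULL) {
  sr <- spec$sample_rate
  n_per <- round(sr * spec$syllable_duration_ms / 1000)
  target <- spec_rms(spec)
  tokens <- stream$tokens
  get_provided <- function(id) {
    if (!id %in% names(syllable_audio))
      stop_ss("no audio provided for syllable '", id, "'")
    w <- syllable_audio[[id]]
    if (is.character(w)) w <- read_wav(w)$samples
    if (is.matrix(w)) {
      if (ncol(w) > 1) stop_ss("syllable audio must be mono: ", id)
      w <- as.numeric(w)
    }
    L <- length(w)
    if (L == 0) stop_ss("empty syllable audio: ", id)
    if (abs(L - n_per) / n_per <= 0.20) {
      w <- approx(seq_len(L), w, xout = seq(1, L, length.out = n_per))$y
    } else if (L > n_per) {
      w <- cos_ramp(w[seq_len(n_per)], sr)
    } else {
      w <- c(cos_ramp(w, sr), numeric(n_per - L))
    }
    normalize_rms(w, target)
  }
  uniq <- unique(tokens)
  cache <- list()
  out <- numeric(n_per * length(tokens))
  for (t in seq_along(tokens)) {
    id <- tokens[t]
    f0 <- if (!is.null(pitch_tracks)) pitch_tracks[[t]] else NULL
    w <- if (!is.null(syllable_audio)) {
      if (is.null(cache[[id]])) cache[[id]] <- get_provided(id)
      cache[[id]]
    } else if (is.null(f0)) {
      if (is.null(cache[[id]]))
        cache[[id]] <- normalize_rms(
          synth_syllable(id, n_per, sr, manner = syllable_manner(stream, id)),
          target)
      cache[[id]]
    } else {
      normalize_rms(
        synth_syllable(id, n_per, sr, f0_track = f0,
                       manner = syllable_manner(stream, id)),
        target)
    }
    out[(t - 1L) * n_per + seq_len(n_per)] <- w
  }
  structure(out, sample_rate = sr, syllable_samples = n_per)
}

#' Resample a pitch contour onto stream windows
#'
#' The contour (arbitrary duration) is linearly interpolated onto each
#' window — one syllable, or one whole word (its S syllables share one
#' interpolated curve, split into per-syllable segments).  Endpoints are
#' preserved.  The result can be passed to [render_stream_audio()] to
#' drive the synthesis fundamental; for user-provided recordings only
#' these contour tracks are exported (no resynthesis of recordings).
#'
#' @param stream A `stream`.
#' @param contour Numeric vector of pitch samples (Hz), or a data frame
#'   with columns `time_s`, `f0_hz`.
#' @param window `"syllable"` or `"word"`.
#' @param points_per_syllable Samples per syllable in the output tracks.
#' @return List (length = stream length) of per-syllable f0 vectors.
#' @export
apply_pitch_contour <- function(stream, contour,
                                window = c("syllable", "word"),
                                points_per_syllable = 64) {
  window <- match.arg(window)
  if (is.data.frame(contour)) contour <- contour$f0_hz
  contour <- as.numeric(contour)
  if (any(contour <= 0) || !length(contour))
    stop_ss("pitch contour must be positive")
  resamp <- function(m) {
    if (length(contour) == 1L) return(rep(contour, m))
    approx(seq(0, 1, length.out = length(contour)), contour,
           xout = seq(0, 1, length.out = m))$y
  }
  T_ <- length(stream$tokens)
  if (window == "syllable") {
    one <- resamp(points_per_syllable)
    return(rep(list(one), T_))
  }
  if (all(is.na(stream$word_position)))
    stop_ss("word-window contour needs word annotations")
  S <- stream$lexicon$S
  curve <- resamp(points_per_syllable * S)
  tracks <- vector("list", T_)
  for (t in seq_len(T_)) {
    p <- stream$word_position[t]
    tracks[[t]] <- curve[(p - 1L) * points_per_syllable +
                           seq_len(points_per_syllable)]
  }
  tracks
}

#' Export pitch tracks as CSV
#'
#' Columns `time_s`, `f0_hz`, flattened over the stream.
#'
#' @param tracks Output of [apply_pitch_contour()].
#' @param spec An [audio_spec()] (for timing).
#' @param path CSV path.
#' @export
write_pitch_tracks <- function(tracks, spec, path) {
  dur <- spec$syllable_duration_ms / 1000
  pts <- length(tracks[[1]])
  df <- do.call(rbind, lapply(seq_along(tracks), function(t)
    data.frame(time_s = (t - 1) * dur + seq(0, dur, length.out = pts),
               f0_hz = tracks[[t]])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

fft_lowpass <- function(x, sr, cutoff) {
  n <- length(x)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * sr / n
  keep <- pmin(freqs, sr - freqs) <= cutoff
  Re(fft(X * keep, inverse = TRUE) / n)
}

#' Amplitude modulation spectrum of a waveform
#'
#' Envelope = magnitude of the analytic signal, low-passed at 30 Hz and
#' downsampled to 1000 Hz; the mean-removed envelope's power spectrum is
#' computed over its full duration, so frequency resolution is
#' 1/duration (<= 0.02 Hz for streams of 50 s and longer).
#'
#' @param waveform Numeric waveform (>= 10 s).
#' @param sample_rate Hz; defaults to the waveform's attribute.
#' @return A `mod_spectrum`: list with `freq` (Hz), `power`, `resolution`.
#' @export
amplitude_modulation_spectrum <- function(waveform, sample_rate = NULL) {
  sr <- sample_rate %||% attr(waveform, "sample_rate")
  if (is.null(sr)) stop_ss("sample_rate required")
  dur <- length(waveform) / sr
  if (dur < 10) stop_ss("waveform too short (< 10 s) for a meaningful ",
                        "low-frequency modulation spectrum")
  env <- Mod(analytic_signal(as.numeric(waveform)))
  env <- fft_lowpass(env, sr, 30)
  fs <- 1000
  t_out <- seq(0, dur - 1 / fs, by = 1 / fs)
  env_d <- approx((seq_along(env) - 1) / sr, env, xout = t_out)$y
  env_d <- env_d - mean(env_d)
  n <- length(env_d)
  pw <- Mod(fft(env_d))^2 / n
  nyq <- floor(n / 2)
  structure(list(freq = (seq_len(nyq) - 1) * fs / n,
                 power = pw[seq_len(nyq)],
                 resolution = fs / n),
            class = "mod_spectrum")
}

#' Peak frequency of a modulation spectrum in a band
#'
#' @param spectrum A `mod_spectrum`.
#' @param band Numeric length-2 band limits in Hz.
#' @param exclude Optional frequencies to mask out (+/- `exclude_tol` Hz).
#' @param exclude_tol Mask half-width, Hz.
#' @return List with `freq` (argmax) and `power`.
#' @export
am_peak <- function(spectrum, band, exclude = NULL, exclude_tol = 0.1) {
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!is.null(exclude))
    for (f in exclude) sel <- sel & abs(spectrum$freq - f) > exclude_tol
  if (!any(sel)) stop_ss("empty band")
  f <- spectrum$freq[sel]; p <- spectrum$power[sel]
  i <- which.max(p)
  list(freq = f[i], power = p[i])
}

#' Power at (the bin nearest) a frequency
#'
#' @param spectrum A `mod_spectrum`.
#' @param freq Frequency, Hz.
#' @export
am_power_at <- function(spectrum, freq) {
  spectrum$power[which.min(abs(spectrum$freq - freq))]
}

#' Write / read mono WAV files
#'
#' Minimal RIFF/WAVE support (no audio package is available in this
#' stack): 32-bit IEEE float or 16-bit PCM, mono.
#'
#' @param samples Numeric vector in \[-1, 1\].
#' @param path File path.
#' @param sample_rate Hz.
#' @param bits 32 (float) or 16 (PCM).
#' @export
write_wav <- function(samples, path, sample_rate = 44100, bits = 32) {
  samples <- as.numeric(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt <- if (bits == 32) 3L else 1L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(samples, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(-1, pmin(1, samples)) * 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop_ss("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop_ss("not a WAVE file")
  fmt <- NULL; sr <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      if (bits == 32 && fmt == 3) {
        samples <- readBin(con, numeric(), n = sz / 4, size = 4,
                           endian = "little")
      } else if (bits == 16 && fmt == 1) {
        samples <- readBin(con, integer(), n = sz / 2, size = 2,
                           endian = "little") / 32768
      } else stop_ss("unsupported WAV format (", fmt, "/", bits, " bit)")
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(samples)) stop_ss("no data chunk in ", path)
  if (channels != 1) stop_ss("only mono WAV is supported")
  list(samples = samples, sample_rate = sr, bits = bits)
}
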