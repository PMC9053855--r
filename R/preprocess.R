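#' Multichannel neural recording container
#'
#' @param data channel x sample numeric matrix (microvolts)
#' @param fs sampling rate in Hz
#' @param channel_meta data.frame with one row per channel: `id`, `region`
#'   (one of HG, PT, STG, other) and logical `include`; a default is built
#'   when omitted
#' @return object of class `recording`
#' @export
recording <- function(data, fs, channel_meta = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), all(is.finite(data)), fs > 0)
  if (is.null(channel_meta)) {
    channel_meta <- data.frame(
      id = sprintf("ch%02d", seq_len(nrow(data))),
      region = "other", include = TRUE
    )
  }
  stopifnot(nrow(channel_meta) == nrow(data),
            all(channel_meta$region %in% c("HG", "PT", "STG", "other")))
  structure(list(data = data, fs = fs, channel_meta = channel_meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' High-gamma envelope container
#'
#' @param env channel x frame nonnegative matrix
#' @param frame_rate frame rate in Hz (100 for this pipeline)
#' @param channel_meta per-channel metadata (as in [recording()])
#' @return object of class `hg_envelope`
#' @export
hg_envelope <- function(env, frame_rate = 100, channel_meta = NULL) {
  env <- as.matrix(env)
  stopifnot(all(is.finite(env)), all(env >= -1e-12), frame_rate > 0)
  env[env < 0] <- 0
  structure(list(env = env, frame_rate = frame_rate,
                 channel_meta = channel_meta),
            class = "hg_envelope")
}

# Second-order IIR notch (constrained biquad) at f0 with the given -3 dB
# bandwidth, applied zero-phase.
notch_filter <- function(x, fs, f0, bw = 1) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) * sinh(log(2) / 2 * (bw / f0) * w0 / sin(w0))
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::filtfilt(signal::Arma(b = b / a[1], a = a / a[1]), x)
}

#' Standardize a raw recording: resample to 512 Hz, remove drift and line noise
#'
#' Applies the fixed conditioning chain: polyphase resampling to 512 Hz, a
#' first-order Butterworth high-pass at 1 Hz (removes DC drift) and
#' second-order IIR notch filters of 1 Hz bandwidth at 60 Hz and its
#' harmonics up to 240 Hz. All filters run forward-backward (zero phase) so
#' event latencies are preserved. Recordings below 512 Hz are refused
#' rather than upsampled.
#'
#' @param rec a [recording()] with `fs >= 512`
#' @param target_fs output rate (Hz), default 512
#' @param hp_cutoff high-pass cutoff (Hz), default 1
#' @param line_freq line frequency (Hz), default 60; harmonics up to 240 Hz
#'   (or Nyquist) are notched
#' @return a standardized [recording()] at `target_fs`
#' @export
standardize <- function(rec, target_fs = 512, hp_cutoff = 1, line_freq = 60) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs < target_fs) {
    stop("recording rate ", rec$fs, " Hz below ", target_fs,
         " Hz; upsampling is refused")
  }
  harmonics <- seq(line_freq, min(240, target_fs / 2 - 5), by = line_freq)
  hp <- signal::butter(1, hp_cutoff / (target_fs / 2), type = "high")
  out <- t(apply(rec$data, 1, function(x) {
    x <- resample_fft(x, rec$fs, target_fs)
    x <- signal::filtfilt(hp, x)
    for (f0 in harmonics) x <- notch_filter(x, target_fs, f0)
    x
  }))
  recording(out, target_fs, rec$channel_meta)
}

#' High-gamma envelope of a standardized recording
#'
#' Filters each channel into `n_bands` contiguous bands spanning 70-150 Hz
#' (equal width by default; fourth-order Butterworth band-pass, zero
#' phase), takes the magnitude of the analytic signal (Hilbert transform)
#' of each band, averages the band envelopes, and resamples the result to
#' 100 Hz with an anti-aliased polyphase resampler.
#'
#' @param rec a standardized [recording()] at 512 Hz
#' @param band_lims high-gamma range in Hz, default `c(70, 150)`
#' @param n_bands number of sub-bands, default 8
#' @param spacing `"equal"` (default) or `"log"` band spacing
#' @param frame_rate output envelope rate, default 100 Hz
#' @return an [hg_envelope()] at `frame_rate`
#' @export
high_gamma <- function(rec, band_lims = c(70, 150), n_bands = 8,
                       spacing = c("equal", "log"), frame_rate = 100) {
  stopifnot(inherits(rec, "recording"), rec$fs > 2 * band_lims[2])
  spacing <- match.arg(spacing)
  if (ncol(rec$data) < 3 * rec$fs / band_lims[1]) {
    stop("recording shorter than the band-pass filter transient")
  }
  edges <- if (spacing == "equal") {
    seq(band_lims[1], band_lims[2], length.out = n_bands + 1)
  } else {
    exp(seq(log(band_lims[1]), log(band_lims[2]), length.out = n_bands + 1))
  }
  filters <- lapply(seq_len(n_bands), function(b) {
    signal::butter(2, c(edges[b], edges[b + 1]) / (rec$fs / 2), type = "pass")
  })
  env <- t(apply(rec$data, 1, function(x) {
    e <- rowMeans(sapply(filters, function(f) {
      hilbert_envelope(signal::filtfilt(f, x))
    }))
    pmax(resample_fft(e, rec$fs, frame_rate), 0)
  }))
  hg_envelope(env, frame_rate, rec$channel_meta)
}

#' Select sound-responsive sites by t test with FDR correction
#'
#' For each channel, compares envelope frames during sound against frames
#' during silence with a two-sample t test, then applies the
#' Benjamini-Hochberg procedure across channels at FDR level `q`.
#'
#' @param env an [hg_envelope()]
#' @param sound_frames integer vector of frame indices during sound
#' @param silence_frames integer vector of frame indices during silence
#' @param q FDR level, default 0.01
#' @param var_equal passed to [stats::t.test()]; default `FALSE` (Welch)
#' @return data.frame with one row per channel: `channel`, `t`, `p`,
#'   `q_value`, `responsive`
#' @export
select_responsive <- function(env, sound_frames, silence_frames, q = 0.01,
                              var_equal = FALSE) {
  stopifnot(inherits(env, "hg_envelope"),
            length(sound_frames) > 1, length(silence_frames) > 1)
  n_frames <- ncol(env$env)
  if (any(c(sound_frames, silence_frames) < 1) ||
      any(c(sound_frames, silence_frames) > n_frames)) {
    stop("an interval lies outside the recording (", n_frames, " frames)")
  }
  res <- t(apply(env$env, 1, function(x) {
    tt <- stats::t.test(x[sound_frames], x[silence_frames],
                        var.equal = var_equal)
    c(tt$statistic, tt$p.value)
  }))
  q_value <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(
    channel = seq_len(nrow(res)),
    t = res[, 1],
    p = res[, 2],
    q_value = q_value,
    responsive = q_value <= q
  )
}
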