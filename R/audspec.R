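#' Auditory spectrogram container
#'
#' Time x band matrix of nonnegative band energies from the cochlear-model
#' front-end, with log-spaced center frequencies and a fixed frame rate.
#'
#' @param energies time x band nonnegative matrix
#' @param band_centers strictly increasing band center frequencies (Hz)
#' @param frame_rate frame rate in Hz
#' @return object of class `auditory_spectrogram`
#' @export
auditory_spectrogram <- function(energies, band_centers, frame_rate = 100) {
  energies <- as.matrix(energies)
  stopifnot(
    ncol(energies) == length(band_centers),
    all(is.finite(energies)), all(energies >= 0),
    all(diff(band_centers) > 0),
    frame_rate > 0
  )
  structure(
    list(energies = energies, band_centers = as.numeric(band_centers),
         frame_rate = frame_rate),
    class = "auditory_spectrogram"
  )
}

#' @export
print.auditory_spectrogram <- function(x, ...) {
  cat(sprintf(
    "auditory_spectrogram: %d frames x %d bands @ %g Hz, %.0f-%.0f Hz\n",
    nrow(x$energies), ncol(x$energies), x$frame_rate,
    min(x$band_centers), max(x$band_centers)))
  invisible(x)
}

#' @export
dim.auditory_spectrogram <- function(x) dim(x$energies)

#' Cochlear-model auditory spectrogram of a waveform
#'
#' Converts audio to a time-frequency representation with a bank of
#' gammatone-style constant-Q filters spaced equally on a logarithmic
#' frequency axis. Each band is realized by complex demodulation to
#' baseband followed by a fourth-order cascade of one-pole low-pass
#' filters (a gammatone envelope detector, asymmetric around the center
#' frequency on a linear axis as cochlear filters are). Band envelopes are
#' averaged into frames at `frame_rate` and passed through a compressive
#' nonlinearity.
#'
#' The filter span and compression are deliberate front-end choices, not
#' physiological claims: the span is 50 Hz to `min(0.4 * fs, 8000)` Hz,
#' covering the speech range, and the default compression is the cube
#' root, standard cochlear-model practice. The front-end is pluggable:
#' anything producing a valid [auditory_spectrogram()] can feed the STRF
#' stage.
#'
#' @param samples mono waveform (numeric vector)
#' @param fs sampling rate in Hz, at least 8000
#' @param n_bands number of filters (default 128)
#' @param f_min lowest center frequency (Hz)
#' @param f_max highest center frequency (Hz); default `min(0.4 * fs, 8000)`
#' @param q filter quality factor (center frequency / bandwidth)
#' @param frame_rate output frame rate (Hz)
#' @param compression exponent applied to band energies (1 = linear,
#'   default 1/3)
#' @return an [auditory_spectrogram()] with `n_bands` bands
#' @export
cochleagram <- function(samples, fs, n_bands = 128, f_min = 50,
                        f_max = min(0.4 * fs, 8000), q = 8,
                        frame_rate = 100, compression = 1 / 3) {
  stopifnot(is.numeric(samples), fs >= 8000, n_bands >= 2,
            f_min > 0, f_max > f_min, f_max <= fs / 2)
  if (length(samples) == 0L) stop("empty waveform")
  centers <- exp(seq(log(f_min), log(f_max), length.out = n_bands))
  n <- length(samples)
  n_frames <- ceiling(n / fs * frame_rate)
  frame_of <- pmin(floor((seq_len(n) - 1) / fs * frame_rate) + 1L, n_frames)
  t <- (seq_len(n) - 1) / fs
  energies <- matrix(0, n_frames, n_bands)
  counts <- tabulate(frame_of, n_frames)
  for (k in seq_len(n_bands)) {
    fc <- centers[k]
    # demodulate to baseband; 4 cascaded one-pole low-pass stages give a
    # 4th-order gammatone envelope with bandwidth fc / q
    z <- samples * exp(-2i * pi * fc * t)
    a <- exp(-2 * pi * (fc / q) / fs)
    b <- 1 - a
    zr <- Re(z); zi <- Im(z)
    for (s in 1:4) {
      zr <- stats::filter(b * zr, a, method = "recursive")
      zi <- stats::filter(b * zi, a, method = "recursive")
    }
    env <- sqrt(zr^2 + zi^2)
    energies[, k] <- rowsum(env, frame_of)[, 1] / counts
  }
  energies <- energies^compression
  auditory_spectrogram(energies, centers, frame_rate)
}

#' Reduce an auditory spectrogram to fewer frequency bands
#'
#' Averages contiguous groups of input bands, the standard step before
#' receptive-field fitting to limit the number of free parameters (e.g.
#' 128 -> 16). Output band centers are the geometric means of each group.
#'
#' @param spec an [auditory_spectrogram()]
#' @param n_out number of output bands (default 16), at most the input count
#' @return an [auditory_spectrogram()] with `n_out` bands
#' @export
reduce_bands <- function(spec, n_out = 16) {
  stopifnot(inherits(spec, "auditory_spectrogram"))
  n_in <- ncol(spec$energies)
  if (n_out > n_in) stop("n_out (", n_out, ") exceeds input band count (", n_in, ")")
  if (n_out == n_in) return(spec)
  group <- band_groups(n_in, n_out)
  e <- sapply(seq_len(n_out), function(g) {
    rowMeans(spec$energies[, group == g, drop = FALSE])
  })
  centers <- sapply(seq_len(n_out), function(g) {
    exp(mean(log(spec$band_centers[group == g])))
  })
  auditory_spectrogram(e, centers, spec$frame_rate)
}

# Contiguous, near-equal-size assignment of n_in bands to n_out groups.
band_groups <- function(n_in, n_out) {
  ceiling(seq_len(n_in) / n_in * n_out)
}
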