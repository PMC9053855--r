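#' Evaluate an expression under a local RNG seed
#'
#' Every stochastic operation in the package draws from a generator that is
#' seeded per call and restored afterwards, so results are bit-reproducible
#' given `(parameters, seed)` and calls never disturb the caller's RNG state.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Analytic-signal envelope via the Hilbert transform
#'
#' Computes `|x + i H(x)|` with the frequency-domain construction of the
#' analytic signal (positive frequencies doubled, negative zeroed).
#'
#' @param x real numeric vector
#' @return nonnegative envelope, same length as `x`
#' @export
hilbert_envelope <- function(x) {
  stopifnot(is.numeric(x), length(x) > 0L)
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 16-bit PCM audio; samples are
#' returned scaled to `[-1, 1]`.
#'
#' @param path file path
#' @return list with `samples` (numeric vector) and `fs` (Hz)
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL
  n_channels <- NULL
  bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      n_channels <- fmt[2]
      fs <- readBin(packBits(intToBits(fmt[3:4]), "raw")[c(1:2, 9:10)],
                    "integer", 1, size = 4, endian = "little")
      bits <- fmt[8]
      if (bits != 16L) stop("only 16-bit WAV supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  x <- samples / 32768
  if (n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = n_channels))
  }
  list(samples = x, fs = fs)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in `[-1, 1]` (clipped otherwise)
#' @param fs sampling rate in Hz
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, fs, path) {
  stopifnot(is.numeric(samples), length(samples) > 0L, fs > 0)
  x <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  n_bytes <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")   # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")  # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample a signal in the frequency domain
#'
#' Rate conversion by Fourier-domain truncation/zero-padding: exactly
#' unit passband gain, zero phase, and ideal anti-aliasing (content above
#' the smaller Nyquist is removed). Appropriate for offline analysis of
#' whole recordings; edge effects are confined to a few samples at the
#' boundaries.
#'
#' @param x numeric vector
#' @param fs_in,fs_out input and output sampling rates (Hz)
#' @return resampled vector of length `round(length(x) * fs_out / fs_in)`
#' @export
resample_fft <- function(x, fs_in, fs_out) {
  stopifnot(is.numeric(x), fs_in > 0, fs_out > 0)
  if (fs_in == fs_out) return(x)
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  m <- min(n, n_out)
  kmax <- floor((m - 1) / 2)
  xf <- stats::fft(x)
  yf <- complex(n_out)
  yf[1] <- xf[1]
  if (kmax > 0) {
    yf[2:(kmax + 1)] <- xf[2:(kmax + 1)]
    yf[(n_out - kmax + 1):n_out] <- xf[(n - kmax + 1):n]
  }
  Re(stats::fft(yf, inverse = TRUE)) / n
}

# Soft-threshold operator used by the STRF sparseness stage.
soft_threshold <- function(w, thresh) {
  sign(w) * pmax(abs(w) - thresh, 0)
}
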