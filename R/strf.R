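#' Fit a spectrotemporal receptive field by normalized reverse correlation
#'
#' Estimates the linear kernel mapping a (16-band) auditory spectrogram to
#' one site's high-gamma envelope. The estimator is normalized reverse
#' correlation: the stimulus autocorrelation matrix, ridge-shrunk by
#' `lambda`, is applied to the stimulus-response cross-correlation,
#'
#' \deqn{w = (X'X + \lambda I)^{-1} X'y,}
#'
#' where `X` holds lagged copies of the spectrogram. A sparseness operator
#' then soft-thresholds the kernel at `s * max(|w|)`. Both hyperparameters
#' are chosen by cross-validation over a declared grid, with contiguous
#' temporal blocks as folds (so autocorrelated frames never straddle a
#' train/test split); the reported `fit_score` is the mean held-out
#' prediction correlation at the selected pair. `lambda` values are scaled
#' by the mean diagonal of `X'X`, so the grid is stimulus-level invariant.
#'
#' @param stimulus an [auditory_spectrogram()] aligned with the response
#'   (same 100 Hz rate and length)
#' @param response numeric envelope vector for one site
#' @param lags_ms maximum lag in ms (default 300; lag grid starts at 0 and
#'   steps by the frame period)
#' @param folds number of contiguous cross-validation blocks (default 5)
#' @param lambda_grid relative ridge grid (default `10^(-4:1)`)
#' @param sparseness_grid soft-threshold fractions (default
#'   `c(0, 0.05, 0.1, 0.2)`)
#' @return object of class `strf_model`: `kernel` (lag x band), `lags_ms`,
#'   `bands` (center Hz), `reg_params` (`lambda`, `sparseness`),
#'   `fit_score`, and the full CV score grid
#' @export
fit_strf <- function(stimulus, response, lags_ms = 300, folds = 5,
                     lambda_grid = 10^seq(-4, 1),
                     sparseness_grid = c(0, 0.05, 0.1, 0.2)) {
  fit_strf_multi(stimulus, matrix(response, ncol = 1), lags_ms, folds,
                 lambda_grid, sparseness_grid)[[1]]
}

#' Fit STRFs for many sites sharing one stimulus
#'
#' Same estimator as [fit_strf()], but the lagged design matrix and its
#' per-fold autocorrelation are computed once and reused across sites,
#' which is much faster when dozens of sites saw the same stimulus.
#'
#' @param stimulus an [auditory_spectrogram()]
#' @param responses frame x site matrix of envelopes
#' @inheritParams fit_strf
#' @return list of `strf_model`, one per column of `responses`
#' @export
fit_strf_multi <- function(stimulus, responses, lags_ms = 300, folds = 5,
                           lambda_grid = 10^seq(-4, 1),
                           sparseness_grid = c(0, 0.05, 0.1, 0.2)) {
  stopifnot(inherits(stimulus, "auditory_spectrogram"))
  responses <- as.matrix(responses)
  s <- stimulus$energies
  n <- nrow(s)
  if (nrow(responses) != n) {
    stop("stimulus has ", n, " frames but responses have ", nrow(responses))
  }
  lag_step <- 1000 / stimulus$frame_rate
  n_lags <- floor(lags_ms / lag_step) + 1L
  p <- n_lags * ncol(s)
  if (n < folds * p / 4) stop("too little data for ", folds, " folds")
  x <- lagged_design(s, n_lags)
  # per-fold sufficient statistics; train = total - held-out block
  block <- cut(seq_len(n), folds, labels = FALSE)
  xtx_b <- lapply(seq_len(folds), function(f) crossprod(x[block == f, , drop = FALSE]))
  xty_b <- lapply(seq_len(folds), function(f) {
    crossprod(x[block == f, , drop = FALSE], responses[block == f, , drop = FALSE])
  })
  xtx <- Reduce(`+`, xtx_b)
  xty <- Reduce(`+`, xty_b)
  lam_scale <- mean(diag(xtx)) * (folds - 1) / folds # mean diag of a train XtX
  eig <- lapply(seq_len(folds), function(f) eigen(xtx - xtx_b[[f]], symmetric = TRUE))
  n_sites <- ncol(responses)
  grid <- expand.grid(lambda = lambda_grid, s = sparseness_grid)
  scores <- array(0, c(nrow(grid), folds, n_sites))
  for (f in seq_len(folds)) {
    v <- eig[[f]]$vectors
    d <- eig[[f]]$values
    vt_xty <- crossprod(v, xty - xty_b[[f]])
    x_val <- x[block == f, , drop = FALSE]
    y_val <- responses[block == f, , drop = FALSE]
    for (li in seq_along(lambda_grid)) {
      w <- v %*% (vt_xty / (d + lambda_grid[li] * lam_scale))
      for (si in seq_along(sparseness_grid)) {
        gi <- which(grid$lambda == lambda_grid[li] &
                      grid$s == sparseness_grid[si])
        for (ch in seq_len(n_sites)) {
          ws <- soft_threshold(w[, ch], sparseness_grid[si] * max(abs(w[, ch])))
          pred <- x_val %*% ws
          scores[gi, f, ch] <- safe_cor(pred, y_val[, ch])
        }
      }
    }
  }
  eig_all <- eigen(xtx, symmetric = TRUE)
  lapply(seq_len(n_sites), function(ch) {
    mean_scores <- rowMeans(matrix(scores[, , ch], nrow = nrow(grid)))
    best <- which.max(mean_scores)
    lam <- grid$lambda[best]
    spars <- grid$s[best]
    w <- eig_all$vectors %*%
      (crossprod(eig_all$vectors, xty[, ch]) /
         (eig_all$values + lam * mean(diag(xtx))))
    w <- soft_threshold(w, spars * max(abs(w)))
    kernel <- matrix(w, nrow = n_lags, byrow = TRUE)
    cv_grid <- cbind(grid, score = mean_scores)
    structure(list(
      kernel = kernel,
      lags_ms = (seq_len(n_lags) - 1) * lag_step,
      bands = stimulus$band_centers,
      reg_params = c(lambda = lam, sparseness = spars),
      fit_score = mean_scores[best],
      cv_grid = cv_grid
    ), class = "strf_model")
  })
}

# Design matrix with columns ordered lag-major: for frame t the row is
# (S[t, 1..B], S[t-1, 1..B], ..., S[t-L+1, 1..B]); pre-stimulus frames are
# zero.
lagged_design <- function(s, n_lags) {
  n <- nrow(s)
  b <- ncol(s)
  x <- matrix(0, n, n_lags * b)
  for (l in seq_len(n_lags)) {
    rows <- l:n
    x[rows, ((l - 1) * b + 1):(l * b)] <- s[rows - l + 1, , drop = FALSE]
  }
  x
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(as.numeric(a), as.numeric(b))
}

#' @export
print.strf_model <- function(x, ...) {
  cat(sprintf(
    "strf_model: %d lags (0-%g ms) x %d bands; lambda=%g, s=%g, CV r=%.3f\n",
    nrow(x$kernel), max(x$lags_ms), ncol(x$kernel),
    x$reg_params["lambda"], x$reg_params["sparseness"], x$fit_score))
  invisible(x)
}

#' Tuning summary: best frequency and latency of the excitatory region
#'
#' Finds the largest 4-connected region of kernel entries that are
#' positive and exceed `threshold_frac` of the kernel maximum (the
#' excitatory region), then takes its energy-weighted center of gravity:
#' the centroid along the frequency axis is the best frequency (mapped to
#' Hz through the band centers) and the centroid along the lag axis is
#' the response latency.
#'
#' @param model a `strf_model` (or any list with `kernel`, `lags_ms`,
#'   `bands`)
#' @param threshold_frac fraction of the kernel maximum defining the
#'   excitatory region (default 0.5)
#' @return object of class `tuning_summary`: `best_frequency` (Hz),
#'   `best_band` (fractional band index), `latency` (ms),
#'   `excitatory_mask` (logical lag x band), `bandwidth_bands` (spectral
#'   extent of the mask, a broadband index); `NULL` fields and class
#'   `tuning_absent` when the kernel has no positive entry
#' @export
tuning_summary <- function(model, threshold_frac = 0.5) {
  k <- model$kernel
  if (all(k <= 0)) {
    return(structure(list(reason = "no excitatory region"),
                     class = "tuning_absent"))
  }
  mask <- largest_connected_region(k > 0 & k >= threshold_frac * max(k))
  w <- k * mask
  w <- w / sum(w)
  band_idx <- sum(w %*% seq_len(ncol(k)))
  lat <- sum(rowSums(w) * model$lags_ms)
  bands <- model$bands
  if (is.null(bands)) bands <- seq_len(ncol(k)) # index scale when centers unknown
  bf_hz <- exp(stats::approx(seq_along(bands), log(bands),
                             xout = band_idx, rule = 2)$y)
  structure(list(
    best_frequency = bf_hz,
    best_band = band_idx,
    latency = lat,
    excitatory_mask = mask,
    bandwidth_bands = sum(colSums(mask) > 0)
  ), class = "tuning_summary")
}

# Largest 4-connected TRUE component of a logical matrix (flood fill).
largest_connected_region <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        queue <- list(c(i, j))
        lab[i, j] <- cur
        while (length(queue) > 0) {
          cell <- queue[[1]]
          queue <- queue[-1]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            ni <- cell[1] + d[1]
            nj <- cell[2] + d[2]
            if (ni >= 1 && ni <= nrow(m) && nj >= 1 && nj <= ncol(m) &&
                m[ni, nj] && lab[ni, nj] == 0L) {
              lab[ni, nj] <- cur
              queue[[length(queue) + 1]] <- c(ni, nj)
            }
          }
        }
      }
    }
  }
  if (cur == 0L) return(m & FALSE)
  sizes <- tabulate(lab[lab > 0], cur)
  lab == which.max(sizes)
}
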