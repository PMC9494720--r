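# Pre-movement window extraction, morphological zero-drift removal, [-1, 1]
# normalization and rectangular-window power spectra.

#' Extract the pre-movement window of a recording
#'
#' Returns the \code{n} samples immediately preceding movement onset for every
#' channel. Only this window feeds the rest of the pipeline: motion intention
#' must be decoded from activity strictly before the first step.
#'
#' @param recording A \code{nirs_recording} (see \code{\link{read_recording}}),
#'   or any list with elements \code{samples} (channels x time matrix) and
#'   \code{onset_index} (number of pre-movement samples, i.e. the 0-based
#'   index of the first movement sample).
#' @param n Window length in samples (default 180).
#' @return A channels x \code{n} matrix.
#' @export
extract_premovement <- function(recording, n = 180L) {
  samples <- recording$samples
  onset <- recording$onset_index
  n <- as.integer(n)
  if (is.null(samples) || is.null(onset)) {
    stop("recording must carry 'samples' and 'onset_index'", call. = FALSE)
  }
  if (onset < n) {
    stop("pre-movement window of ", n, " samples exceeds available ",
         onset, " pre-onset samples", call. = FALSE)
  }
  samples[, (onset - n + 1L):onset, drop = FALSE]
}

# Sliding minimum with replicated edges (flat structuring element, length k).
# x is a channels x time matrix; the erosion acts along time for every row.
.slide_min <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- ncol(x)
  xp <- cbind(x[, rep(1L, h), drop = FALSE], x,
              x[, rep(n, h), drop = FALSE])
  acc <- xp[, 1L:n, drop = FALSE]
  for (s in seq_len(k - 1L)) acc <- pmin(acc, xp[, (1L + s):(n + s),
                                                 drop = FALSE])
  acc
}

.slide_max <- function(x, k) -.slide_min(-x, k)

.morph_open <- function(x, k) .slide_max(.slide_min(x, k), k)
.morph_close <- function(x, k) .slide_min(.slide_max(x, k), k)

#' Remove zero drift with a mathematical morphology filter
#'
#' Estimates the baseline as the average of the close-open and open-close
#' compositions with a flat structuring element and subtracts it. Structures
#' wider than the element (slow drift, offsets) are absorbed into the baseline;
#' oscillations faster than the element survive in the residual. Edges are
#' handled by replication, which in particular lets slow slopes within half an
#' element of the window end pass partially into the residual.
#'
#' @param x Numeric vector (one channel's time series), or a channels x time
#'   matrix (filtered per row).
#' @param se_length Structuring element length in samples; odd, between 3 and
#'   \code{length(x) - 1}. The default 31 (about 4 s at a 0.13 s sampling
#'   period) spans several samples of the fastest in-band oscillation.
#' @return The drift-removed series, same shape as \code{x}.
#' @export
remove_zero_drift <- function(x, se_length = 31L) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  k <- as.integer(se_length)
  if (k %% 2L != 1L || k < 3L || k >= ncol(X)) {
    stop("se_length must be odd and in [3, length(x)); got ", k, call. = FALSE)
  }
  baseline <- 0.5 * (.morph_close(.morph_open(X, k), k) +
                     .morph_open(.morph_close(X, k), k))
  out <- X - baseline
  if (vec_in) drop(out) else out
}

#' Normalize a time series to [-1, 1]
#'
#' Applies \code{2 * (x - min) / (max - min) - 1}, mapping the minimum to -1
#' and the maximum to +1. Used per channel on the drift-removed pre-movement
#' window to damp amplitude differences between subjects.
#'
#' @param x Numeric vector with \code{max(x) > min(x)}.
#' @return Numeric vector in \code{[-1, 1]}.
#' @export
normalize_signal <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1L] >= rng[2L]) {
    stop("cannot normalize a constant series (zero range)", call. = FALSE)
  }
  2 * (x - rng[1L]) / (rng[2L] - rng[1L]) - 1
}

#' One-sided periodogram with a rectangular window
#'
#' Raw periodogram (no taper, no detrending) used to identify the active
#' frequency range of the hemoglobin oscillations. Power is scaled so that the
#' sum over all one-sided bins equals the mean square of the signal
#' (Parseval's identity).
#'
#' @param x Numeric vector, length at least 8.
#' @param sampling_period Sampling period in seconds (default 0.13).
#' @return A list of class \code{"nirs_spectrum"} with \code{frequencies}
#'   (Hz, from 0 to Nyquist) and \code{power}.
#' @export
power_spectrum <- function(x, sampling_period = 0.13) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("input too short for a spectrum (need >= 8 samples)",
                   call. = FALSE)
  X <- stats::fft(x)
  p2 <- Mod(X)^2 / n^2                   # two-sided, sums to mean(x^2)
  half <- n %/% 2L
  idx <- seq_len(half + 1L)              # 0 .. Nyquist (or just below)
  power <- p2[idx]
  fold <- 2L:(if (n %% 2L == 0L) half else half + 1L)
  power[fold] <- power[fold] + p2[n + 2L - fold]
  structure(list(frequencies = (idx - 1L) / (n * sampling_period),
                 power = power, sampling_period = sampling_period),
            class = "nirs_spectrum")
}

#' @export
print.nirs_spectrum <- function(x, ...) {
  pk <- which.max(x$power[-1L]) + 1L
  cat("Periodogram: ", length(x$power), " bins, resolution ",
      format(x$frequencies[2L], digits = 4), " Hz, peak at ",
      format(x$frequencies[pk], digits = 4), " Hz\n", sep = "")
  invisible(x)
}

#' Preprocess one channel for feature extraction
#'
#' Convenience composition: morphological drift removal followed by
#' normalization to \code{[-1, 1]}.
#'
#' @inheritParams remove_zero_drift
#' @return Numeric vector in \code{[-1, 1]}.
#' @keywords internal
preprocess_channel <- function(x, se_length = 31L) {
  normalize_signal(remove_zero_drift(x, se_length))
}
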