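# Independent brute-force oracles used across test files.

# O(N * k) sliding min/max with replicated edges.
brute_slide_min <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- pmin(pmax((i - h):(i + h), 1L), n)
    min(x[idx])
  }, numeric(1))
}
brute_slide_max <- function(x, k) -brute_slide_min(-x, k)

brute_morph_baseline <- function(x, k) {
  er <- function(v) brute_slide_min(v, k)
  di <- function(v) brute_slide_max(v, k)
  open <- function(v) di(er(v))
  close <- function(v) er(di(v))
  0.5 * (close(open(x)) + open(close(x)))
}

# Exhaustive rank-threshold mask: k best cells, ties by ascending
# (band, channel) cell index (band-major flattening).
brute_rank_mask <- function(M, k, decreasing = FALSE) {
  v <- as.vector(t(M))
  ord <- order(if (decreasing) -v else v, seq_along(v))
  mask <- numeric(length(v))
  mask[ord[seq_len(k)]] <- 1
  t(matrix(mask, ncol(M), nrow(M)))
}

# Exhaustive region counting by membership scan.
brute_region_counts <- function(mask, regions) {
  out <- matrix(0, nrow(mask), length(regions))
  colnames(out) <- names(regions)
  for (b in seq_len(nrow(mask))) {
    for (r in seq_along(regions)) {
      out[b, r] <- sum(mask[b, regions[[r]]])
    }
  }
  out
}

# FFT band-energy fraction of a signal within [lo, hi) Hz.
fft_band_fraction <- function(x, lo, hi, sampling_period) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (0:(n - 1)) / (n * sampling_period)
  f <- pmin(f, 1 / sampling_period - f)  # fold to [0, Nyquist]
  sum(p[f >= lo & f < hi]) / sum(p)
}

make_recording <- function(samples, onset = ncol(samples), subject = "S01",
                           state = "SP-LD", kind = "totalHb", dt = 0.13) {
  structure(list(subject_id = subject, state = state, signal_kind = kind,
                 samples = samples, sampling_period = dt,
                 onset_index = as.integer(onset)),
            class = "nirs_recording")
}
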