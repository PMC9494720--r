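# Subband slope features: first-difference slopes of the reconstructed
# subbands, averaged over the last few samples before movement onset.

#' Pre-onset slope features of reconstructed subbands
#'
#' For each subband signal, takes the per-sample first difference as the
#' local rate of change and averages the \code{n_avg} values immediately
#' before onset (8 points is about one second at a 0.13 s sampling period).
#'
#' @param bands A \code{wp_subbands} object (see
#'   \code{\link{wavelet_packet_subbands}}), or a list of numeric vectors /
#'   channel x time matrices.
#' @param onset_index Number of pre-onset samples in the band signals (0-based
#'   index of the first movement sample). Defaults to the full signal length:
#'   slopes are then read at the very end of the window.
#' @param n_avg Number of slope values averaged (default 8).
#' @return If the bands are vectors, a numeric vector with one feature per
#'   band (signal units per sample); if matrices, a bands x channels matrix.
#' @export
slope_features <- function(bands, onset_index = NULL, n_avg = 8L) {
  if (inherits(bands, "wp_subbands")) bands <- bands$bands
  n_avg <- as.integer(n_avg)
  one <- function(b) {
    vec <- is.null(dim(b))
    B <- if (vec) matrix(b, nrow = 1L) else b
    n <- ncol(B)
    onset <- if (is.null(onset_index)) n else as.integer(onset_index)
    if (onset < n_avg + 1L) {
      stop("need at least n_avg + 1 pre-onset samples (onset ", onset,
           ", n_avg ", n_avg, ")", call. = FALSE)
    }
    if (onset > n) stop("onset_index beyond signal length", call. = FALSE)
    d <- B[, 2:n, drop = FALSE] - B[, 1:(n - 1L), drop = FALSE]
    # column k of d is the slope at 0-based sample index k; average the
    # slopes at indices [onset - n_avg, onset)
    rowMeans(d[, (onset - n_avg):(onset - 1L), drop = FALSE])
  }
  res <- lapply(bands, one)
  if (length(res[[1L]]) == 1L) unlist(res) else do.call(rbind, res)
}

#' Band x channel slope-feature matrix of one recording
#'
#' Runs the full single-trial feature path: extract the pre-movement window,
#' remove zero drift per channel, normalize per channel to [-1, 1], decompose
#' with wavelet packets, reconstruct the \code{n_bands} lowest subbands and
#' read the pre-onset slope feature of every channel in every band.
#'
#' @param recording A \code{nirs_recording}.
#' @param window Pre-movement window length in samples (default 180).
#' @param se_length Structuring element of the morphology filter.
#' @param level,n_bands,wavelet Wavelet packet parameters
#'   (see \code{\link{wavelet_packet_subbands}}).
#' @param n_avg Slope averaging length (see \code{\link{slope_features}}).
#' @return A \code{n_bands} x channels matrix (class
#'   \code{"band_feature_matrix"}) with rows \code{pd1..}, columns
#'   \code{ch1..}, and attributes \code{subject_id}, \code{state},
#'   \code{signal_kind}.
#' @export
compute_feature_matrix <- function(recording, window = 180L, se_length = 31L,
                                   level = 7L, n_bands = 6L, wavelet = "db4",
                                   n_avg = 8L) {
  W <- extract_premovement(recording, window)
  Z <- remove_zero_drift(W, se_length)
  rmin <- apply(Z, 1L, min)
  rmax <- apply(Z, 1L, max)
  if (any(rmax <= rmin)) {
    stop("constant drift-removed channel: cannot normalize", call. = FALSE)
  }
  P <- 2 * (Z - rmin) / (rmax - rmin) - 1  # per-row [-1, 1] normalization
  wp <- wavelet_packet_subbands(P, level = level, n_bands = n_bands,
                                wavelet = wavelet,
                                sampling_period = recording$sampling_period)
  F <- slope_features(wp, n_avg = n_avg)  # bands x channels
  dimnames(F) <- list(paste0("pd", seq_len(nrow(F))),
                      paste0("ch", seq_len(ncol(F))))
  structure(F, class = c("band_feature_matrix", "matrix"),
            subject_id = recording$subject_id, state = recording$state,
            signal_kind = recording$signal_kind)
}

#' Feature matrices for a whole cohort
#'
#' @param cohort A \code{nirs_cohort}.
#' @param ... Passed to \code{\link{compute_feature_matrix}}.
#' @return A nested list \code{features[[subject]][[signal_kind]][[state]]}
#'   of band x channel feature matrices.
#' @export
cohort_feature_matrices <- function(cohort, ...) {
  out <- list()
  for (rec in cohort) {
    out[[rec$subject_id]][[rec$signal_kind]][[rec$state]] <-
      compute_feature_matrix(rec, ...)
  }
  out
}
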