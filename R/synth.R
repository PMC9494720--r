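# Synthetic fNIRS cohort generator. Emulates the statistical structure the
# analysis assumes -- slow zero drift, broadband 0-0.18 Hz oscillations, white
# noise and class-discriminative pre-movement slopes localized to chosen
# (subband, channel, signal kind) cells -- so every downstream stage can be
# exercised against known ground truth.

#' Specify a class-discriminative injected effect
#'
#' Describes where and how strongly the synthetic cohort separates classes: a
#' pre-movement ramp whose per-sample slope differs between classes, injected
#' as a sinusoid at the centre frequency of the target subband with a linearly
#' growing envelope (so the effect is band-limited and expresses itself as a
#' subband slope just before movement onset).
#'
#' @param subband Target subband index, 1-6 (0.03 Hz-wide bands tiling
#'   0-0.18 Hz).
#' @param channel Target channel, 1-22.
#' @param signal_kind \code{"totalHb"} or \code{"oxy_minus_deoxy"}.
#' @param offsets Named numeric vector of per-class slope offsets in signal
#'   units per sample; names are gait states (\code{"SP-LD"}, ...) or class
#'   labels (\code{"LD"}, \code{"MD"}, \code{"HD"}, \code{"SP"}, \code{"MP"},
#'   \code{"LP"}). States without a matching name get offset 0.
#' @return A list of class \code{"effect_spec"}.
#' @export
effect_spec <- function(subband, channel, signal_kind = "totalHb", offsets) {
  subband <- as.integer(subband)
  channel <- as.integer(channel)
  if (subband < 1L || subband > 6L) stop("subband must be in 1..6",
                                         call. = FALSE)
  if (channel < 1L || channel > 22L) stop("channel must be in 1..22",
                                          call. = FALSE)
  if (!signal_kind %in% c("totalHb", "oxy_minus_deoxy")) {
    stop("signal_kind must be 'totalHb' or 'oxy_minus_deoxy'", call. = FALSE)
  }
  if (is.null(names(offsets)) || any(!nzchar(names(offsets)))) {
    stop("offsets must be a named numeric vector", call. = FALSE)
  }
  structure(list(subband = subband, channel = channel,
                 signal_kind = signal_kind, offsets = offsets),
            class = "effect_spec")
}

#' Configuration of a synthetic cohort
#'
#' Defaults mirror the study's recording protocol: 31 subjects, the six gait
#' states, 22 channels at a 0.13 s sampling period, and at least 180 samples
#' of pre-movement rest per trial.
#'
#' @param n_subjects Number of subjects.
#' @param states Gait states to generate (default all six).
#' @param n_channels Number of channels (22 whenever the region map is used).
#' @param sampling_period Sampling period in seconds.
#' @param pre_onset_samples Samples of rest before movement onset (>= 180).
#' @param post_onset_samples Samples after onset.
#' @param drift_amplitude Scale of the slow zero drift (random walk with knots
#'   at sub-0.005 Hz spacing plus offset), in signal units.
#' @param noise_sd White measurement-noise standard deviation, signal units.
#' @param osc_sd Standard deviation of the broadband 0-0.18 Hz oscillatory
#'   background (sum of 1/f-weighted random-phase sinusoids), signal units.
#' @param effect_map List of \code{\link{effect_spec}} objects (possibly
#'   empty: no class-discriminative signal).
#' @param subject_sd Between-subject variability: each subject scales all
#'   injected effects by \code{max(0, rnorm(1, 1, subject_sd))}.
#' @param signal_kinds Which signal kinds to generate.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return A list of class \code{"synth_config"}.
#' @export
synth_config <- function(n_subjects = 31L, states = gait_states(),
                         n_channels = 22L, sampling_period = 0.13,
                         pre_onset_samples = 200L, post_onset_samples = 60L,
                         drift_amplitude = 0.5, noise_sd = 0.05,
                         osc_sd = 0.5, effect_map = list(),
                         subject_sd = 0.2,
                         signal_kinds = c("totalHb", "oxy_minus_deoxy"),
                         seed = 1L) {
  states <- as.character(states)
  for (s in states) gait_state(s)
  if (anyDuplicated(states)) stop("duplicate states", call. = FALSE)
  if (n_subjects < 1L || n_channels < 1L || post_onset_samples < 0L) {
    stop("non-positive cohort dimensions", call. = FALSE)
  }
  if (pre_onset_samples < 180L) {
    stop("pre_onset_samples must be >= 180 (preprocessing window requirement)",
         call. = FALSE)
  }
  if (sampling_period <= 0) stop("sampling_period must be > 0", call. = FALSE)
  stopifnot(all(signal_kinds %in% c("totalHb", "oxy_minus_deoxy")))
  for (e in effect_map) {
    if (!inherits(e, "effect_spec")) {
      stop("effect_map entries must be effect_spec objects", call. = FALSE)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), states = states,
    n_channels = as.integer(n_channels), sampling_period = sampling_period,
    pre_onset_samples = as.integer(pre_onset_samples),
    post_onset_samples = as.integer(post_onset_samples),
    drift_amplitude = drift_amplitude, noise_sd = noise_sd, osc_sd = osc_sd,
    effect_map = effect_map, subject_sd = subject_sd,
    signal_kinds = signal_kinds, seed = as.integer(seed)
  ), class = "synth_config")
}

# Per-class slope offset of one effect spec for a given state (0 if the spec
# does not address this state).
.effect_offset <- function(effect, state) {
  keys <- c(state, state_class(state, "walking_speed"),
            state_class(state, "step_length"))
  hit <- keys[keys %in% names(effect$offsets)]
  if (length(hit)) unname(effect$offsets[[hit[1L]]]) else 0
}

# Band-limited ramp: sinusoid at the subband centre frequency with a linearly
# growing envelope, scaled so its per-sample derivative at onset equals a.
.effect_component <- function(a, subband, n, onset, sampling_period) {
  w <- 1 / (2 * sampling_period) / 128
  fc <- (subband - 0.5) * w
  i <- 0:(n - 1L)
  env <- pmin(i / onset, 1)
  omega <- 2 * pi * fc * sampling_period        # radians per sample
  (a / omega) * env * sin(omega * (i - onset))
}

#' Canonical demonstration effect map
#'
#' The package's reference synthetic conditions: a walking-speed effect in
#' subband 2 (0.03-0.06 Hz) of totalHb channel 15 and a step-length effect in
#' subband 2 of oxyHb-deoxyHb channel 4, each with per-class slope offsets
#' \code{-d, 0, +d}. The default \code{d = 0.08} signal units per sample
#' yields single-trial feature separations of roughly twice the trial-level
#' feature noise (a moderate, clearly recoverable but far-from-ceiling
#' effect); see the methods vignette for the calibration rationale.
#'
#' @param d Per-class slope offset magnitude (signal units per sample).
#' @return List of two \code{\link{effect_spec}} objects.
#' @export
demo_effect_map <- function(d = 0.08) {
  list(
    effect_spec(2, 15, "totalHb", c(LD = -d, MD = 0, HD = d)),
    effect_spec(2, 4, "oxy_minus_deoxy", c(SP = -d, MP = 0, LP = d))
  )
}

#' Generate a synthetic fNIRS cohort
#'
#' Produces one recording per (subject, state, signal kind). Each channel is
#' the sum of slow drift, a broadband 0-0.18 Hz oscillation, white noise and
#' any injected class effects (see \code{\link{effect_spec}}); onset is at
#' \code{pre_onset_samples}. Fully deterministic for a fixed
#' \code{config$seed}.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list of class \code{"nirs_cohort"} of \code{nirs_recording}
#'   objects, each with fields \code{subject_id}, \code{state},
#'   \code{signal_kind}, \code{samples} (channels x time),
#'   \code{sampling_period}, \code{onset_index}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$pre_onset_samples + config$post_onset_samples
  onset <- config$pre_onset_samples
  dt <- config$sampling_period
  tvec <- (0:(n - 1L)) * dt
  knot_gap <- max(2L, ceiling(1 / (0.005 * dt)))  # < 0.005 Hz drift knots
  n_knots <- ceiling(n / knot_gap) + 1L

  recs <- list()
  for (s in seq_len(config$n_subjects)) {
    subject_id <- sprintf("S%02d", s)
    eff_scale <- max(0, stats::rnorm(1L, 1, config$subject_sd))
    for (state in config$states) {
      for (kind in config$signal_kinds) {
        samples <- matrix(0, config$n_channels, n)
        for (ch in seq_len(config$n_channels)) {
          knots <- config$drift_amplitude *
            (stats::rnorm(1L) + cumsum(stats::rnorm(n_knots)))
          drift <- stats::approx(x = (seq_len(n_knots) - 1L) * knot_gap,
                                 y = knots, xout = 0:(n - 1L))$y
          freqs <- stats::runif(24L, 0.005, 0.18)
          phases <- stats::runif(24L, 0, 2 * pi)
          amps <- 1 / freqs
          amps <- amps * config$osc_sd / sqrt(sum(amps^2) / 2)
          osc <- drop(amps %*% sin(2 * pi * outer(freqs, tvec) + phases))
          noise <- stats::rnorm(n, 0, config$noise_sd)
          x <- drift + osc + noise
          for (eff in config$effect_map) {
            if (eff$signal_kind != kind || eff$channel != ch) next
            a <- .effect_offset(eff, state) * eff_scale
            if (a != 0) {
              x <- x + .effect_component(a, eff$subband, n, onset, dt)
            }
          }
          samples[ch, ] <- x
        }
        recs[[length(recs) + 1L]] <- structure(
          list(subject_id = subject_id, state = state, signal_kind = kind,
               samples = samples, sampling_period = dt, onset_index = onset),
          class = "nirs_recording")
      }
    }
  }
  structure(recs, class = "nirs_cohort", config = config)
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat("fNIRS recording: subject ", x$subject_id, ", state ", x$state,
      " (", x$signal_kind, "), ", nrow(x$samples), " channels x ",
      ncol(x$samples), " samples, onset at ", x$onset_index, "\n", sep = "")
  invisible(x)
}

#' @export
print.nirs_cohort <- function(x, ...) {
  subs <- unique(vapply(x, `[[`, character(1), "subject_id"))
  cat("fNIRS cohort: ", length(x), " recordings, ", length(subs),
      " subjects\n", sep = "")
  invisible(x)
}

#' Subjects present in a cohort
#' @param cohort A \code{nirs_cohort}.
#' @return Character vector of subject ids.
#' @export
cohort_subjects <- function(cohort) {
  unique(vapply(cohort, `[[`, character(1), "subject_id"))
}

#' Restrict a cohort to a set of subjects
#' @param cohort A \code{nirs_cohort}.
#' @param subjects Character vector of subject ids to keep.
#' @return A \code{nirs_cohort}.
#' @export
cohort_subset <- function(cohort, subjects) {
  keep <- vapply(cohort, function(r) r$subject_id %in% subjects, logical(1))
  structure(cohort[keep], class = "nirs_cohort",
            config = attr(cohort, "config"))
}
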