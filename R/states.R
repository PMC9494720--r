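# Gait-state definitions, the step-length / walking-speed class groupings and
# the fixed 22-region spatial map over the 22 optode channels.

.all_states <- c("SP-LD", "SP-MD", "MP-LD", "MP-MD", "MP-HD", "LP-MD")

#' The six gait states
#'
#' The study's protocol crosses step length (SP = small, MP = mid, LP = large)
#' with walking speed (LD = low, MD = mid, HD = high), but only six of the
#' nine combinations are walked: SP-LD, SP-MD, MP-LD, MP-MD, MP-HD and LP-MD.
#'
#' @return Character vector of the six valid state labels.
#' @export
gait_states <- function() .all_states

#' Validate a gait-state label
#' @param state Character label such as \code{"SP-LD"}.
#' @return The label, invisibly; errors on an invalid combination.
#' @export
gait_state <- function(state) {
  if (!state %in% .all_states) {
    stop("invalid gait state '", state, "'; valid states: ",
         paste(.all_states, collapse = ", "), call. = FALSE)
  }
  invisible(state)
}

#' Class of a gait state along one dimension
#'
#' Collapses the six gait states into three classes of the chosen dimension:
#' for \code{"walking_speed"} the classes are LD (SP-LD, MP-LD),
#' MD (SP-MD, MP-MD, LP-MD) and HD (MP-HD); for \code{"step_length"} they are
#' SP (SP-LD, SP-MD), MP (MP-LD, MP-MD, MP-HD) and LP (LP-MD).
#'
#' @param state Character vector of gait-state labels.
#' @param dimension \code{"walking_speed"} or \code{"step_length"}.
#' @return Character vector of class labels.
#' @export
state_class <- function(state, dimension = c("walking_speed", "step_length")) {
  dimension <- match.arg(dimension)
  bad <- setdiff(state, .all_states)
  if (length(bad)) stop("invalid gait state(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  part <- if (dimension == "walking_speed") 2L else 1L
  vapply(strsplit(state, "-", fixed = TRUE), `[[`, character(1), part)
}

#' Classes and their constituent states for one dimension
#'
#' @inheritParams state_class
#' @return Named list: for each class label, the character vector of gait
#'   states it contains.
#' @export
state_classes <- function(dimension = c("walking_speed", "step_length")) {
  dimension <- match.arg(dimension)
  cls <- state_class(.all_states, dimension)
  lv <- if (dimension == "walking_speed") c("LD", "MD", "HD")
        else c("SP", "MP", "LP")
  stats::setNames(lapply(lv, function(k) .all_states[cls == k]), lv)
}

.region_channels <- list(
  Re1 = c(1, 3, 6),    Re2 = c(3, 6, 8),    Re3 = c(6, 8, 11),
  Re4 = c(8, 11, 13),  Re5 = c(11, 13, 16), Re6 = c(13, 16, 18),
  Re7 = c(16, 18, 21), Re8 = c(1, 2, 4),    Re9 = c(4, 6, 7),
  Re10 = c(6, 7, 9),   Re11 = c(9, 11, 12), Re12 = c(11, 12, 14),
  Re13 = c(14, 16, 17), Re14 = c(16, 17, 19), Re15 = c(19, 21, 22),
  Re16 = c(2, 5, 7),   Re17 = c(5, 7, 10),  Re18 = c(7, 10, 12),
  Re19 = c(10, 12, 15), Re20 = c(12, 15, 17), Re21 = c(15, 17, 20),
  Re22 = c(17, 20, 22)
)

#' The 22-region spatial map
#'
#' Each of the 22 regions Re1..Re22 groups exactly three of the 22 optode
#' channels; regions overlap, so that feature extraction can follow the most
#' responsive channel within a neighbourhood rather than a fixed channel,
#' making the features robust to differences in head size.
#'
#' @return Named list mapping \code{"Re1"}..\code{"Re22"} to integer triples
#'   of channel indices.
#' @export
region_map <- function() .region_channels

# The two independent frequency parts: bands 1-3 (0-0.09 Hz), 4-6 (0.09-0.18).
.band_part <- function(band) ifelse(band <= 3L, 1L, 2L)
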