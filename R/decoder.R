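# The fitted-model interface: gait_decoder() runs selection cascade + GA +
# SVM on a training cohort and returns a classed object with the usual
# methods.

#' Fit a walking-intention decoder
#'
#' End-to-end fit for one classification dimension: computes band x channel
#' slope features for every training recording, runs the mean/CV selection
#' cascade with cross-subject frequency statistics, merges contiguous bands,
#' filters candidates by one-way ANOVA, searches feature subsets with the
#' adaptive GA (leave-one-subject-out SVM accuracy as fitness) and finally
#' trains one multiclass SVM on all training subjects using the best subset.
#'
#' @param cohort A \code{nirs_cohort} (training recordings), or a
#'   precomputed nested feature list from
#'   \code{\link{cohort_feature_matrices}}.
#' @param dimension \code{"walking_speed"} or \code{"step_length"}.
#' @param subjects Training subject ids (default: all in the cohort).
#' @param ga A \code{\link{ga_params}} object; set \code{ga = NULL} to skip
#'   the GA and use every ANOVA-retained spec.
#' @param threshold,alpha Selection-cascade parameters
#'   (see \code{\link{select_features}}).
#' @param window,se_length,wavelet,level,n_bands,n_avg Feature parameters
#'   (see \code{\link{compute_feature_matrix}}), used when \code{cohort} is a
#'   cohort of recordings.
#' @param cost SVM cost parameter.
#' @return An object of class \code{"gait_decoder"} with the selected
#'   feature specs, the GA search trace, the fitted SVM and the training
#'   LOSO accuracy. Methods: \code{print}, \code{summary}, \code{coef}
#'   (selected specs as a data frame), \code{predict}, \code{plot} (GA
#'   trace).
#' @examples
#' \donttest{
#' cfg <- synth_config(n_subjects = 6, signal_kinds = "totalHb", seed = 42,
#'   effect_map = list(effect_spec(5, 15, "totalHb",
#'                                 c(LD = -0.02, MD = 0, HD = 0.02))))
#' fit <- gait_decoder(generate_cohort(cfg), "walking_speed",
#'                     ga = ga_params(population_size = 10,
#'                                    n_iterations = 100, seed = 7))
#' print(fit)
#' }
#' @export
gait_decoder <- function(cohort,
                         dimension = c("walking_speed", "step_length"),
                         subjects = NULL, ga = ga_params(),
                         threshold = 0.6, alpha = 0.05,
                         window = 180L, se_length = 31L, wavelet = "db4",
                         level = 7L, n_bands = 6L, n_avg = 8L, cost = 1) {
  dimension <- match.arg(dimension)
  features <- if (inherits(cohort, "nirs_cohort")) {
    cohort_feature_matrices(cohort, window = window, se_length = se_length,
                            level = level, n_bands = n_bands,
                            wavelet = wavelet, n_avg = n_avg)
  } else cohort
  if (is.null(subjects)) subjects <- names(features)
  features <- features[subjects]

  sel <- select_features(features, dimension, subjects,
                         threshold = threshold, alpha = alpha)
  specs <- sel$specs
  if (!length(specs)) {
    stop("selection cascade retained no feature specs; ",
         "the cohort carries no reproducible class-discriminative signal",
         call. = FALSE)
  }
  inst <- instance_feature_matrix(features, specs, subjects)
  labels <- state_class(inst$state, dimension)

  if (!is.null(ga) && length(specs) > 1L) {
    fitness_fn <- function(mask)
      loso_fitness(mask, inst$X, inst$subject, labels, cost)
    search <- ga_select(length(specs), fitness_fn, ga)
    mask <- search$mask
  } else {
    mask <- rep(TRUE, length(specs))
    search <- list(mask = mask,
                   fitness = loso_fitness(mask, inst$X, inst$subject,
                                          labels, cost),
                   trace = numeric(0), n_evaluations = 1L)
  }

  lev <- names(state_classes(dimension))
  Xm <- inst$X[, mask, drop = FALSE]
  sc <- .standardize_fit(Xm)
  svm_fit <- .svm_fit(.standardize_apply(Xm, sc),
                      factor(labels, levels = lev), cost)
  structure(list(
    dimension = dimension, subjects = subjects,
    candidates = sel$candidates, specs = specs, mask = mask,
    selected = specs[mask],
    ga = search, loso_accuracy = search$fitness,
    svm = svm_fit, scaling = sc, levels = lev, cost = cost,
    feature_params = list(window = window, se_length = se_length,
                          wavelet = wavelet, level = level,
                          n_bands = n_bands, n_avg = n_avg),
    threshold = threshold, alpha = alpha
  ), class = "gait_decoder")
}

#' @export
print.gait_decoder <- function(x, ...) {
  cat("Walking-intention decoder (", x$dimension, ")\n", sep = "")
  cat("  training subjects: ", length(x$subjects),
      "; candidate specs: ", length(x$specs),
      "; selected by GA: ", length(x$selected), "\n", sep = "")
  cat("  training LOSO accuracy: ",
      sprintf("%.2f%%", 100 * x$loso_accuracy), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gait_decoder <- function(object, ...) {
  print(object)
  cat("  selected feature vectors:\n")
  for (sp in object$selected) {
    cat("    ", format_feature_spec(sp), " [", sp$polarity, ", ",
        sp$signal_kind, "]\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.gait_decoder <- function(object, ...) {
  data.frame(
    serial = seq_along(object$selected),
    notation = vapply(object$selected, format_feature_spec, character(1)),
    polarity = vapply(object$selected, `[[`, character(1), "polarity"),
    signal_kind = vapply(object$selected, `[[`, character(1), "signal_kind"),
    stringsAsFactors = FALSE
  )
}

#' Predict gait classes for new subjects
#'
#' @param object A fitted \code{gait_decoder}.
#' @param newdata A \code{nirs_cohort} or a nested feature list; subjects
#'   must be disjoint from the training subjects.
#' @param ... Unused.
#' @return A \code{gait_accuracy} object (predictions, accuracy and
#'   confusion matrix against the known states of \code{newdata}).
#' @export
predict.gait_decoder <- function(object, newdata, ...) {
  features <- if (inherits(newdata, "nirs_cohort")) {
    fp <- object$feature_params
    cohort_feature_matrices(newdata, window = fp$window,
                            se_length = fp$se_length, level = fp$level,
                            n_bands = fp$n_bands, wavelet = fp$wavelet,
                            n_avg = fp$n_avg)
  } else newdata
  overlap <- intersect(object$subjects, names(features))
  if (length(overlap)) {
    stop("test subjects overlap the training cohort: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  inst <- instance_feature_matrix(features, object$selected)
  yte <- factor(state_class(inst$state, object$dimension),
                levels = object$levels)
  pred <- stats::predict(object$svm,
                         .standardize_apply(inst$X, object$scaling))
  pred <- factor(pred, levels = object$levels)
  structure(list(
    accuracy = mean(pred == yte), n_correct = sum(pred == yte),
    n_total = length(yte),
    confusion = table(truth = yte, predicted = pred),
    predicted = pred, truth = yte, subject = inst$subject,
    dimension = object$dimension
  ), class = "gait_accuracy")
}

#' Plot the GA search trace of a fitted decoder
#'
#' @param x A \code{gait_decoder}.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.gait_decoder <- function(x, ...) {
  tr <- x$ga$trace
  if (!length(tr)) {
    warning("no GA trace recorded (GA was skipped)")
    return(invisible(x))
  }
  graphics::plot(seq_along(tr), tr, type = "s", xlab = "generation",
                 ylab = "best LOSO accuracy",
                 main = paste("Adaptive GA search,", x$dimension), ...)
  invisible(x)
}
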