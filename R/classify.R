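# SVM classification of gait classes from selected feature vectors:
# leave-one-subject-out fitness for the GA, and the final train/test
# evaluation.

#' Per-instance feature matrix for a set of feature specs
#'
#' Each (subject, gait state) pair is one instance; the value of a spec is
#' extracted from the subject's single-state band x channel matrix of the
#' spec's signal kind.
#'
#' @param features Nested feature list from
#'   \code{\link{cohort_feature_matrices}}.
#' @param specs List of feature specs.
#' @param subjects Subject ids to include (default all).
#' @return List with \code{X} (instances x specs numeric matrix),
#'   \code{subject} and \code{state} (character vectors per instance).
#' @export
instance_feature_matrix <- function(features, specs,
                                    subjects = names(features)) {
  rows <- list(); subj <- character(0); st <- character(0)
  for (sub in subjects) {
    kinds <- features[[sub]]
    states <- names(kinds[[1L]])
    for (state in states) {
      vals <- vapply(specs, function(sp)
        extract_feature_values(kinds[[sp$signal_kind]][[state]], sp),
        numeric(1))
      rows[[length(rows) + 1L]] <- vals
      subj <- c(subj, sub); st <- c(st, state)
    }
  }
  list(X = do.call(rbind, rows), subject = subj, state = st)
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

.standardize_apply <- function(X, sc) {
  sweep(sweep(X, 2L, sc$mu, "-"), 2L, sc$sd, "/")
}

.svm_fit <- function(X, y, cost = 1) {
  e1071::svm(x = X, y = factor(y), kernel = "radial", cost = cost,
             gamma = 1 / ncol(X), scale = FALSE)
}

#' Leave-one-subject-out SVM fitness
#'
#' For each training subject in turn, trains a multiclass RBF SVM (one-vs-one,
#' C = 1, gamma = 1/n_features; features standardized with training-fold
#' statistics only) on the remaining subjects' instances and scores the
#' held-out subject's instances. The fitness of a feature-subset mask is the
#' mean per-fold accuracy.
#'
#' @param mask Logical vector selecting columns of \code{X} (at least one
#'   \code{TRUE}).
#' @param X Instances x features numeric matrix.
#' @param subject Subject id per instance (defines the folds).
#' @param labels Class label per instance.
#' @param cost SVM cost parameter (default 1).
#' @return Mean LOSO accuracy in [0, 1].
#' @export
loso_fitness <- function(mask, X, subject, labels, cost = 1) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty feature mask", call. = FALSE)
  Xs <- X[, mask, drop = FALSE]
  labels <- factor(labels)
  folds <- unique(subject)
  acc <- vapply(folds, function(hold) {
    tr <- subject != hold
    ytr <- labels[tr]
    if (nlevels(droplevels(ytr)) < nlevels(labels)) {
      stop("class absent from a training fold", call. = FALSE)
    }
    sc <- .standardize_fit(Xs[tr, , drop = FALSE])
    fit <- .svm_fit(.standardize_apply(Xs[tr, , drop = FALSE], sc), ytr, cost)
    pred <- stats::predict(fit,
                           .standardize_apply(Xs[!tr, , drop = FALSE], sc))
    mean(pred == labels[!tr])
  }, numeric(1))
  mean(acc)
}

#' Final train/test evaluation
#'
#' Trains one multiclass SVM on all training subjects' instances (six gait
#' states per subject, relabelled into the three classes of the chosen
#' dimension) and scores the test cohort's instances: 11 test subjects x 6
#' states = 66 test instances at the study's cohort sizes.
#'
#' @param train_features,test_features Nested feature lists from
#'   \code{\link{cohort_feature_matrices}}; subject sets must be disjoint.
#' @param specs Feature specs fixed before seeing the test data.
#' @param dimension \code{"walking_speed"} or \code{"step_length"}.
#' @param cost SVM cost parameter.
#' @return List of class \code{"gait_accuracy"}: \code{accuracy},
#'   \code{n_correct}, \code{n_total}, \code{confusion} (3 x 3, rows = true),
#'   \code{predicted}, \code{truth}, \code{subject}.
#' @export
train_and_test <- function(train_features, test_features, specs,
                           dimension = c("walking_speed", "step_length"),
                           cost = 1) {
  dimension <- match.arg(dimension)
  overlap <- intersect(names(train_features), names(test_features))
  if (length(overlap)) {
    stop("training and test cohorts overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (!length(specs)) stop("no feature specs", call. = FALSE)
  lev <- names(state_classes(dimension))
  tr <- instance_feature_matrix(train_features, specs)
  te <- instance_feature_matrix(test_features, specs)
  ytr <- factor(state_class(tr$state, dimension), levels = lev)
  yte <- factor(state_class(te$state, dimension), levels = lev)
  sc <- .standardize_fit(tr$X)
  fit <- .svm_fit(.standardize_apply(tr$X, sc), ytr, cost)
  pred <- stats::predict(fit, .standardize_apply(te$X, sc))
  pred <- factor(pred, levels = lev)
  structure(list(
    accuracy = mean(pred == yte),
    n_correct = sum(pred == yte),
    n_total = length(yte),
    confusion = table(truth = yte, predicted = pred),
    predicted = pred, truth = yte, subject = te$subject,
    dimension = dimension
  ), class = "gait_accuracy")
}

#' @export
print.gait_accuracy <- function(x, ...) {
  cat("Test accuracy (", x$dimension, "): ",
      sprintf("%.2f%% (%d/%d)", 100 * x$accuracy, x$n_correct, x$n_total),
      "\n", sep = "")
  print(x$confusion)
  invisible(x)
}
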