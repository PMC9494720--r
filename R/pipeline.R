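# File interchange (CSV trials + JSON sidecars/manifest) and the reproducible
# end-to-end pipeline driver.

.trial_basename <- function(subject_id, state, signal_kind) {
  paste(subject_id, state, signal_kind, sep = "_")
}

#' Write a cohort to a directory of CSV trials
#'
#' One CSV per (subject, state, signal kind) with header
#' \code{time,ch1,...,chN}, one JSON sidecar per trial (subject, state,
#' signal kind, onset index, sampling period) and a \code{manifest.json}
#' listing all trials.
#'
#' @param recordings A \code{nirs_cohort} or list of \code{nirs_recording}s
#'   (may be empty: only the manifest is written).
#' @param directory Output directory (created if missing).
#' @return Invisibly, the paths of the written CSV files.
#' @export
write_cohort <- function(recordings, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  entries <- list()
  for (rec in recordings) {
    base <- .trial_basename(rec$subject_id, rec$state, rec$signal_kind)
    csv <- file.path(directory, paste0(base, ".csv"))
    n <- ncol(rec$samples)
    df <- data.frame(time = (0:(n - 1L)) * rec$sampling_period,
                     t(rec$samples))
    names(df) <- c("time", paste0("ch", seq_len(nrow(rec$samples))))
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     csv, row.names = FALSE, quote = FALSE)
    meta <- list(subject_id = rec$subject_id, state = rec$state,
                 signal_kind = rec$signal_kind,
                 sampling_period = rec$sampling_period,
                 onset_index = rec$onset_index,
                 n_channels = nrow(rec$samples))
    jsonlite::write_json(meta, file.path(directory, paste0(base, ".json")),
                         auto_unbox = TRUE, digits = NA)
    entries[[length(entries) + 1L]] <- c(meta, list(file = basename(csv)))
    paths <- c(paths, csv)
  }
  jsonlite::write_json(list(n_trials = length(entries), trials = entries),
                       file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read one recording from a CSV trial file
#'
#' Expects the dialect written by \code{\link{write_cohort}} and a JSON
#' sidecar next to the CSV. Validates the channel count, missing values and
#' the pre-movement window requirement.
#'
#' @param path Path to the trial CSV.
#' @param n_channels Expected channel count (default 22).
#' @return A \code{nirs_recording}.
#' @export
read_recording <- function(path, n_channels = 22L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) {
    stop("missing sidecar metadata: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("time", paste0("ch", seq_len(n_channels)))
  if (!identical(names(df), expected)) {
    stop("malformed header in ", path, ": expected ", length(expected),
         " columns time,ch1..ch", n_channels, ", got ",
         paste(utils::head(names(df), 4), collapse = ","),
         "... (", ncol(df), " columns)", call. = FALSE)
  }
  samples <- t(as.matrix(df[, -1L]))
  if (anyNA(samples)) stop("NaN/missing cells in ", path, call. = FALSE)
  if (is.null(meta$onset_index) || meta$onset_index < 180) {
    stop("onset_index ", meta$onset_index, " < 180 in ", sidecar,
         ": the 180-sample pre-movement window does not exist",
         call. = FALSE)
  }
  dimnames(samples) <- NULL
  structure(list(subject_id = meta$subject_id, state = meta$state,
                 signal_kind = meta$signal_kind, samples = samples,
                 sampling_period = meta$sampling_period,
                 onset_index = as.integer(meta$onset_index)),
            class = "nirs_recording")
}

#' Read a whole cohort directory
#'
#' @param directory Directory written by \code{\link{write_cohort}}.
#' @param n_channels Expected channel count.
#' @return A \code{nirs_cohort}.
#' @export
read_cohort <- function(directory, n_channels = 22L) {
  manifest <- file.path(directory, "manifest.json")
  files <- if (file.exists(manifest)) {
    m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    if (m$n_trials == 0L) character(0)
    else file.path(directory, m$trials$file)
  } else {
    list.files(directory, pattern = "\\.csv$", full.names = TRUE)
  }
  recs <- lapply(files, read_recording, n_channels = n_channels)
  structure(recs, class = "nirs_cohort")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Training and test subject
#' sets must be disjoint.
#'
#' @param train_subjects,test_subjects Character vectors of subject ids.
#' @param window,se_length,level,n_bands,wavelet,n_avg Feature parameters.
#' @param threshold,alpha Selection parameters.
#' @param ga A \code{\link{ga_params}} object (or \code{NULL} to skip the
#'   GA).
#' @param cost SVM cost.
#' @param seed Master seed: the GA seed is derived from it per dimension.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(train_subjects, test_subjects,
                            window = 180L, se_length = 31L, level = 7L,
                            n_bands = 6L, wavelet = "db4", n_avg = 8L,
                            threshold = 0.6, alpha = 0.05,
                            ga = ga_params(), cost = 1, seed = 1L) {
  overlap <- intersect(train_subjects, test_subjects)
  if (length(overlap)) {
    stop("training and test subject sets overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(train_subjects = train_subjects,
                 test_subjects = test_subjects, window = as.integer(window),
                 se_length = as.integer(se_length), level = as.integer(level),
                 n_bands = as.integer(n_bands), wavelet = wavelet,
                 n_avg = as.integer(n_avg), threshold = threshold,
                 alpha = alpha, ga = ga, cost = cost, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Polynomial rolling hash of a serialized object, for the provenance block.
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full decoding pipeline and write reports
#'
#' Executes features -> selection -> GA/SVM for both classification
#' dimensions on a cohort, evaluates on the held-out test subjects, and
#' writes a JSON report per dimension plus a provenance block. Identical
#' seeds give byte-identical reports.
#'
#' @param cohort A \code{nirs_cohort}, or a directory readable by
#'   \code{\link{read_cohort}}.
#' @param config A \code{\link{pipeline_config}}.
#' @param output_dir Directory for the report files.
#' @return Invisibly, a list with the per-dimension \code{gait_decoder} fits
#'   and \code{gait_accuracy} test reports.
#' @export
run_pipeline <- function(cohort, config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  result <- list()
  tryCatch({
    stage <- "features"
    missing <- setdiff(c(config$train_subjects, config$test_subjects),
                       cohort_subjects(cohort))
    if (length(missing)) {
      stop("subjects not present in cohort: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    message("[features] band x channel slope features for ",
            length(cohort), " recordings")
    features <- cohort_feature_matrices(
      cohort, window = config$window, se_length = config$se_length,
      level = config$level, n_bands = config$n_bands,
      wavelet = config$wavelet, n_avg = config$n_avg)

    for (dim_i in seq_along(c("walking_speed", "step_length"))) {
      dimension <- c("walking_speed", "step_length")[dim_i]
      stage <- paste0("select+classify:", dimension)
      message("[select+classify] dimension ", dimension)
      ga <- config$ga
      if (!is.null(ga)) ga$seed <- config$seed + dim_i
      fit <- gait_decoder(features, dimension,
                          subjects = config$train_subjects, ga = ga,
                          threshold = config$threshold, alpha = config$alpha,
                          cost = config$cost)
      test <- predict(fit, features[config$test_subjects])
      report <- list(
        dimension = dimension,
        selected_features = vapply(fit$selected, format_feature_spec,
                                   character(1)),
        polarity = vapply(fit$selected, `[[`, character(1), "polarity"),
        signal_kind = vapply(fit$selected, `[[`, character(1),
                             "signal_kind"),
        training_loso_accuracy = fit$loso_accuracy,
        test_accuracy = test$accuracy,
        n_correct = test$n_correct, n_total = test$n_total,
        confusion = as.data.frame.matrix(unclass(test$confusion)),
        provenance = list(config_hash = .config_hash(config),
                          seed = config$seed,
                          package_version = as.character(
                            utils::packageVersion("nirsgait")))
      )
      jsonlite::write_json(report,
                           file.path(output_dir,
                                     paste0("report_", dimension, ".json")),
                           auto_unbox = TRUE, digits = 12, pretty = TRUE)
      if (length(fit$ga$trace)) {
        utils::write.csv(
          data.frame(generation = seq_along(fit$ga$trace),
                     best_fitness = fit$ga$trace),
          file.path(output_dir, paste0("ga_trace_", dimension, ".csv")),
          row.names = FALSE)
      }
      result[[dimension]] <- list(fit = fit, test = test)
    }
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
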