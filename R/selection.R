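# The multi-stage feature-selection cascade: within-subject mean/CV masks
# (M1-M7), region quantization (M8/M9), cross-subject frequency statistics,
# contiguous-band merging, value extraction and one-way ANOVA filtering.

# Cells are ranked in ascending (band, channel) order for deterministic
# tie-breaks: band-major flattening of a 6 x 22 matrix.
.cell_order_vec <- function(M) as.vector(t(M))

.rank_mask <- function(values, k, decreasing = FALSE) {
  # indicator over cells of the k best values; ties broken by cell index
  ord <- order(if (decreasing) -values else values, seq_along(values))
  mask <- logical(length(values))
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

.unflatten <- function(v, template) {
  M <- matrix(v, nrow = ncol(template), ncol = nrow(template))
  t(M)
}

#' Within-subject selection matrices M1-M7
#'
#' From the band x channel feature matrices of the constituent gait states of
#' one target class (e.g. SP-LD and MP-LD for the low-speed class), computes:
#' M1 the elementwise mean; M2 the absolute coefficient of variation
#' (sample sd / mean); M3 the indicator of the bottom 50\% of CV values
#' (stable cells); M4 / M5 the indicators of the top / bottom 20\% of the
#' mean (strongly activated / inhibited cells); and the key-channel masks
#' M6 = M3 & M4, M7 = M3 & M5.
#'
#' @param mats List of band x channel matrices, one per constituent state.
#'   With a single constituent state the CV is taken as 0 everywhere (no
#'   between-state variability to measure).
#' @param cv_fraction Fraction of cells flagged in M3 (default 0.5).
#' @param mean_fraction Fraction flagged in each of M4 and M5 (default 0.2).
#' @return A list of class \code{"selection_matrices"} with elements
#'   \code{M1}, \code{M2} (numeric matrices) and \code{M3}-\code{M7}
#'   (0/1 matrices). A cell whose mean is exactly zero has CV \code{+Inf} and
#'   is never selected into M3.
#' @export
build_selection_matrices <- function(mats, cv_fraction = 0.5,
                                     mean_fraction = 0.2) {
  if (!length(mats)) stop("no constituent-state matrices", call. = FALSE)
  dims <- dim(mats[[1L]])
  for (m in mats) {
    if (!identical(dim(m), dims)) stop("matrices differ in shape",
                                       call. = FALSE)
  }
  A <- array(unlist(mats), dim = c(dims, length(mats)))
  M1 <- apply(A, c(1, 2), mean)
  if (length(mats) >= 2L) {
    SD <- apply(A, c(1, 2), stats::sd)
  } else {
    SD <- matrix(0, dims[1L], dims[2L])
  }
  M2 <- ifelse(M1 == 0, Inf, abs(SD / M1))
  n_cells <- prod(dims)
  cv_v <- .cell_order_vec(M2)
  mu_v <- .cell_order_vec(M1)
  m3 <- .rank_mask(cv_v, floor(cv_fraction * n_cells))
  m4 <- .rank_mask(mu_v, floor(mean_fraction * n_cells), decreasing = TRUE)
  m5 <- .rank_mask(mu_v, floor(mean_fraction * n_cells))
  M3 <- .unflatten(as.numeric(m3), M1)
  M4 <- .unflatten(as.numeric(m4), M1)
  M5 <- .unflatten(as.numeric(m5), M1)
  dimnames(M1) <- dimnames(M2) <- dimnames(M3) <- dimnames(M4) <-
    dimnames(M5) <- dimnames(mats[[1L]])
  structure(list(M1 = M1, M2 = M2, M3 = M3, M4 = M4, M5 = M5,
                 M6 = M3 * M4, M7 = M3 * M5),
            class = "selection_matrices")
}

#' Quantize key-channel masks into region counts (M8, M9)
#'
#' For every band and every region, counts how many of the region's three
#' channels are flagged as key channels. A region with a nonzero count is a
#' key region.
#'
#' @param M6,M7 0/1 key-channel masks (bands x channels), activation and
#'   inhibition polarity respectively.
#' @param regions Region map as returned by \code{\link{region_map}}.
#' @return List with \code{M8} and \code{M9}: bands x regions count matrices
#'   (entries 0..3).
#' @export
regionize <- function(M6, M7, regions = region_map()) {
  count_regions <- function(M) {
    out <- vapply(regions, function(chs) rowSums(M[, chs, drop = FALSE]),
                  numeric(nrow(M)))
    rownames(out) <- rownames(M)
    out
  }
  list(M8 = count_regions(M6), M9 = count_regions(M7))
}

new_feature_spec <- function(region, polarity, bands, key_counts,
                             signal_kind) {
  structure(list(region = region, polarity = polarity,
                 bands = as.integer(bands), key_counts = as.integer(key_counts),
                 signal_kind = signal_kind),
            class = "feature_spec")
}

#' Render a feature spec in serial notation
#'
#' E.g. \code{"Re4: pd1(1) + pd2(1)"}: region Re4, subbands pd1 and pd2, one
#' key channel in each.
#'
#' @param spec A feature spec (element of the list returned by
#'   \code{\link{cohort_frequency_selection}}).
#' @return Character scalar.
#' @export
format_feature_spec <- function(spec) {
  paste0(spec$region, ": ",
         paste(sprintf("pd%d(%d)", spec$bands, spec$key_counts),
               collapse = " + "))
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(format_feature_spec(x), " [", x$polarity, ", ", x$signal_kind, "]\n",
      sep = "")
  invisible(x)
}

# Mode of a vector of positive counts; ties -> smaller count.
.count_mode <- function(counts) {
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])  # which.max picks first = smallest
}

#' Cross-subject frequency selection of feature regions
#'
#' A (band, region, polarity) cell becomes a feature region if at least
#' 60\% of the training subjects flag it (nonzero key-channel count); with 20
#' subjects that is 12 of 20, and for other cohort sizes the threshold is
#' \code{ceiling(0.6 n)}. The region's key-channel number is the most
#' frequent nonzero per-subject count among the subjects that flagged it
#' (ties resolved toward the smaller count; set
#' \code{key_count_rule = "max"} to take the maximum instead).
#'
#' @param quantized Per-subject list, each element a list with matrices
#'   \code{M8} and \code{M9} as returned by \code{\link{regionize}}.
#' @param threshold Required fraction of subjects (default 0.6).
#' @param signal_kind Signal kind tag carried into the resulting specs.
#' @param key_count_rule \code{"mode"} (default) or \code{"max"}.
#' @return List of single-band feature specs (class \code{"feature_spec"}).
#' @export
cohort_frequency_selection <- function(quantized, threshold = 0.6,
                                       signal_kind = "totalHb",
                                       key_count_rule = c("mode", "max")) {
  key_count_rule <- match.arg(key_count_rule)
  n_sub <- length(quantized)
  if (!n_sub) stop("no subjects", call. = FALSE)
  need <- ceiling(threshold * n_sub)
  regions <- colnames(quantized[[1L]]$M8)
  if (is.null(regions)) regions <- paste0("Re", seq_len(ncol(quantized[[1L]]$M8)))
  n_bands <- nrow(quantized[[1L]]$M8)
  specs <- list()
  for (pol in c("top", "bottom")) {
    mat_name <- if (pol == "top") "M8" else "M9"
    for (b in seq_len(n_bands)) {
      for (r in seq_along(regions)) {
        counts <- vapply(quantized, function(q) q[[mat_name]][b, r],
                         numeric(1))
        sel <- counts > 0
        if (sum(sel) >= need) {
          kc <- if (key_count_rule == "mode") .count_mode(counts[sel])
                else max(counts[sel])
          specs[[length(specs) + 1L]] <-
            new_feature_spec(regions[r], pol, b, kc, signal_kind)
        }
      }
    }
  }
  specs
}

#' Merge contiguous-band feature specs within a frequency part
#'
#' Feature regions selected in adjacent subbands of the same region, polarity
#' and signal kind are combined into one feature vector, but never across the
#' 0.09 Hz boundary between the lower part (pd1-pd3) and the upper part
#' (pd4-pd6).
#'
#' @param specs List of feature specs from one selection run.
#' @return List of feature specs with merged \code{bands}/\code{key_counts}.
#' @export
merge_contiguous_bands <- function(specs) {
  if (!length(specs)) return(specs)
  key <- vapply(specs, function(s)
    paste(s$signal_kind, s$polarity, s$region,
          .band_part(s$bands[1L]), sep = "|"), character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- specs[key == k]
    bands <- vapply(grp, function(s) s$bands[1L], integer(1))
    kcs <- vapply(grp, function(s) s$key_counts[1L], integer(1))
    ord <- order(bands)
    bands <- bands[ord]; kcs <- kcs[ord]
    run_start <- 1L
    for (i in seq_along(bands)) {
      last <- i == length(bands)
      if (last || bands[i + 1L] != bands[i] + 1L) {
        idx <- run_start:i
        g1 <- grp[[1L]]
        out[[length(out) + 1L]] <-
          new_feature_spec(g1$region, g1$polarity, bands[idx], kcs[idx],
                           g1$signal_kind)
        run_start <- i + 1L
      }
    }
  }
  out
}

#' Extract the scalar value of a feature spec from a feature matrix
#'
#' Within each constituent band, takes the mean of the \code{key_count}
#' largest (polarity \code{"top"}) or smallest (\code{"bottom"}) values among
#' the region's three channels; the spec's scalar is the mean over its
#' constituent bands. Following the key-channel idea, the channel carrying
#' the value may differ between subjects and trials.
#'
#' @param M1 Bands x channels matrix (a subject's class-mean matrix, or a
#'   single trial's feature matrix).
#' @param spec A feature spec.
#' @param regions Region map.
#' @return Numeric scalar.
#' @export
extract_feature_values <- function(M1, spec, regions = region_map()) {
  chs <- regions[[spec$region]]
  if (is.null(chs)) stop("unknown region ", spec$region, call. = FALSE)
  per_band <- vapply(seq_along(spec$bands), function(i) {
    k <- spec$key_counts[i]
    if (k > length(chs)) stop("key_count ", k, " exceeds region size",
                              call. = FALSE)
    v <- M1[spec$bands[i], chs]
    v <- sort(v, decreasing = (spec$polarity == "top"))
    mean(v[seq_len(k)])
  }, numeric(1))
  mean(per_band)
}

# One-way ANOVA p-value for two or more groups (standard F distribution).
.anova_p <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) return(1)
  gm <- tapply(values, groups, mean)
  if (all(tapply(values, groups, stats::var) %in% c(0, NA)) &&
      length(unique(gm)) == 1L) {
    return(1)  # zero within-group variance with equal means
  }
  fit <- stats::aov(values ~ groups)
  summary(fit)[[1L]][["Pr(>F)"]][1L]
}

#' ANOVA filter over candidate feature specs
#'
#' For every candidate spec, compares the per-subject feature values of every
#' pair of target classes with a one-way ANOVA; the spec is retained if any
#' pair differs at level \code{alpha}. No multiple-testing correction is
#' applied.
#'
#' @param values_by_class For a single spec: a named list mapping class label
#'   to the numeric vector of per-subject values. Or a list of such lists
#'   (one per spec).
#' @param alpha Significance level (default 0.05).
#' @return For a single spec, a list with \code{retained} (logical) and
#'   \code{p_values} (named per pair); for a list of specs, a logical vector.
#' @export
anova_filter <- function(values_by_class, alpha = 0.05) {
  single <- is.numeric(values_by_class[[1L]])
  one <- function(vbc) {
    cls <- names(vbc)
    if (length(cls) < 2L) stop("need at least 2 classes", call. = FALSE)
    pairs <- utils::combn(cls, 2L, simplify = FALSE)
    p <- vapply(pairs, function(pr) {
      v <- c(vbc[[pr[1L]]], vbc[[pr[2L]]])
      g <- rep(pr, times = c(length(vbc[[pr[1L]]]), length(vbc[[pr[2L]]])))
      .anova_p(v, g)
    }, numeric(1))
    names(p) <- vapply(pairs, paste, character(1), collapse = " vs ")
    list(retained = any(p < alpha), p_values = p)
  }
  if (single) one(values_by_class)
  else vapply(values_by_class, function(v) one(v)$retained, logical(1))
}

#' Run the full selection cascade for one dimension
#'
#' Applies the whole chain -- per-subject M1-M9, cross-subject frequency
#' selection per target class and polarity, contiguous-band merging and
#' ANOVA filtering -- over both signal kinds, and pools the surviving specs
#' into one candidate set (duplicates across classes removed).
#'
#' @param features Nested per-subject feature list from
#'   \code{\link{cohort_feature_matrices}} (\code{[[subject]][[kind]][[state]]}).
#' @param dimension \code{"walking_speed"} or \code{"step_length"}.
#' @param subjects Training subject ids (default: all in \code{features}).
#' @param threshold Cross-subject frequency threshold (default 0.6).
#' @param alpha ANOVA significance level (default 0.05).
#' @param cv_fraction,mean_fraction Mask fractions
#'   (see \code{\link{build_selection_matrices}}).
#' @param key_count_rule See \code{\link{cohort_frequency_selection}}.
#' @return List with \code{specs} (retained feature specs), \code{candidates}
#'   (specs before the ANOVA filter), and \code{class_values} (per retained
#'   spec, the per-class training values used by the filter).
#' @export
select_features <- function(features,
                            dimension = c("walking_speed", "step_length"),
                            subjects = names(features), threshold = 0.6,
                            alpha = 0.05, cv_fraction = 0.5,
                            mean_fraction = 0.2,
                            key_count_rule = "mode") {
  dimension <- match.arg(dimension)
  classes <- state_classes(dimension)
  kinds <- names(features[[subjects[1L]]])
  candidates <- list()
  class_m1 <- list()  # [[kind]][[class]][[subject]] -> M1 matrix
  for (kind in kinds) {
    for (cl in names(classes)) {
      quantized <- list()
      for (sub in subjects) {
        mats <- features[[sub]][[kind]][classes[[cl]]]
        sm <- build_selection_matrices(mats, cv_fraction, mean_fraction)
        class_m1[[kind]][[cl]][[sub]] <- sm$M1
        quantized[[sub]] <- regionize(sm$M6, sm$M7)
      }
      specs <- cohort_frequency_selection(quantized, threshold, kind,
                                          key_count_rule)
      candidates <- c(candidates, merge_contiguous_bands(specs))
    }
  }
  key <- vapply(candidates, function(s)
    paste(s$signal_kind, s$polarity, s$region,
          paste(s$bands, collapse = ","),
          paste(s$key_counts, collapse = ","), sep = "|"), character(1))
  candidates <- candidates[!duplicated(key)]

  class_values <- lapply(candidates, function(sp) {
    stats::setNames(lapply(names(classes), function(cl) {
      vapply(subjects, function(sub)
        extract_feature_values(class_m1[[sp$signal_kind]][[cl]][[sub]], sp),
        numeric(1))
    }), names(classes))
  })
  retained <- if (length(candidates)) anova_filter(class_values, alpha)
              else logical(0)
  list(specs = candidates[retained],
       candidates = candidates,
       class_values = class_values[retained])
}
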