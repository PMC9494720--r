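test_that("mean and CV matrices follow the sample-sd convention", {
  m1 <- matrix(1); m2 <- matrix(3)
  sm <- build_selection_matrices(list(m1, m2))
  expect_equal(sm$M1[1, 1], 2)
  expect_equal(sm$M2[1, 1], sqrt(2) / 2)

  # a zero-mean cell gets infinite CV and is never stability-selected
  a <- matrix(c(-1, 5, 5, 5), 2, 2)
  b <- matrix(c(1, 6, 6, 6), 2, 2)
  sm <- build_selection_matrices(list(a, b))
  expect_identical(sm$M2[1, 1], Inf)
  expect_identical(sm$M3[1, 1], 0)
})

test_that("mask cardinalities are 66/26/26 and match a brute-force oracle", {
  set.seed(51)
  for (rep in 1:5) {
    mats <- replicate(2, matrix(rnorm(132), 6, 22), simplify = FALSE)
    sm <- build_selection_matrices(mats)
    expect_identical(sum(sm$M3), 66)
    expect_identical(sum(sm$M4), 26)
    expect_identical(sum(sm$M5), 26)
    expect_true(all(sm$M6 <= sm$M3) && all(sm$M6 <= sm$M4))
    expect_true(all(sm$M7 <= sm$M3) && all(sm$M7 <= sm$M5))
    expect_equal(unname(sm$M3), brute_rank_mask(sm$M2, 66))
    expect_equal(unname(sm$M4), brute_rank_mask(sm$M1, 26, decreasing = TRUE))
    expect_equal(unname(sm$M5), brute_rank_mask(sm$M1, 26))
    expect_equal(unname(sm$M6), brute_rank_mask(sm$M2, 66) *
                   brute_rank_mask(sm$M1, 26, decreasing = TRUE))
  }

  # identical constituents: zero CV everywhere, tie-break fills 66 cells
  m <- matrix(rnorm(132), 6, 22)
  sm <- build_selection_matrices(list(m, m))
  expect_true(all(sm$M2 == 0))
  expect_identical(sum(sm$M3), 66)
  expect_identical(sum(sm$M3[1:3, ]), 66)  # first 66 cells in band order
})

test_that("region quantization counts key channels within the fixed map", {
  rm <- region_map()
  expect_identical(length(rm), 22L)
  expect_true(all(vapply(rm, length, integer(1)) == 3L))
  expect_identical(rm$Re1, c(1, 3, 6))

  M6 <- matrix(0, 6, 22); M7 <- matrix(0, 6, 22)
  M6[1, c(1, 3)] <- 1
  q <- regionize(M6, M7, rm)
  expect_equal(unname(q$M8[1, "Re1"]), 2)
  expect_true(all(q$M9 == 0))

  M6b <- matrix(0, 6, 22); M6b[2, 6] <- 1
  q2 <- regionize(M6b, M7, rm)
  hit <- names(which(q2$M8[2, ] == 1))
  expect_setequal(hit, c("Re1", "Re2", "Re3", "Re9", "Re10"))
  expect_true(all(q2$M8[2, hit] == 1))

  set.seed(52)
  mask <- matrix(rbinom(132, 1, 0.3), 6, 22)
  q3 <- regionize(mask, mask, rm)
  expect_equal(unname(q3$M8), unname(brute_region_counts(mask, rm)))
  expect_true(all(q3$M8 >= 0 & q3$M8 <= 3))
})

test_that("frequency selection applies the 60% rule and the count mode", {
  mk <- function(count) {
    M8 <- matrix(0, 6, 22, dimnames = list(NULL, names(region_map())))
    M8[2, "Re5"] <- count
    list(M8 = M8, M9 = M8 * 0)
  }
  # 12 of 20 subjects flag the region -> selected
  q <- c(lapply(1:12, function(i) mk(1)), lapply(1:8, function(i) mk(0)))
  specs <- cohort_frequency_selection(q)
  expect_identical(length(specs), 1L)
  expect_identical(specs[[1]]$region, "Re5")
  expect_identical(specs[[1]]$bands, 2L)

  # 11 of 20 -> not selected
  q <- c(lapply(1:11, function(i) mk(1)), lapply(1:9, function(i) mk(0)))
  expect_identical(length(cohort_frequency_selection(q)), 0L)

  # key count is the mode over selecting subjects: {1 x 10, 2 x 4} -> 1
  q <- c(lapply(1:10, function(i) mk(1)), lapply(1:4, function(i) mk(2)),
         lapply(1:6, function(i) mk(0)))
  specs <- cohort_frequency_selection(q)
  expect_identical(specs[[1]]$key_counts, 1L)
  # mode ties resolve toward the smaller count
  q <- c(lapply(1:7, function(i) mk(1)), lapply(1:7, function(i) mk(3)),
         lapply(1:6, function(i) mk(0)))
  expect_identical(cohort_frequency_selection(q)[[1]]$key_counts, 1L)
  # alternative rule: maximum observed count
  expect_identical(
    cohort_frequency_selection(q, key_count_rule = "max")[[1]]$key_counts, 3L)

  # non-20 cohorts recompute the threshold as ceiling(0.6 n)
  q <- c(lapply(1:4, function(i) mk(1)), lapply(1:2, function(i) mk(0)))
  expect_identical(length(cohort_frequency_selection(q)), 1L)  # 4 >= ceil(3.6)
  q <- c(lapply(1:3, function(i) mk(1)), lapply(1:3, function(i) mk(0)))
  expect_identical(length(cohort_frequency_selection(q)), 0L)
})

test_that("contiguous bands merge within a part but never across 0.09 Hz", {
  sp <- function(region, band, kc = 1L, pol = "top", kind = "totalHb")
    nirsgait:::new_feature_spec(region, pol, band, kc, kind)

  m <- merge_contiguous_bands(list(sp("Re4", 1L), sp("Re4", 2L)))
  expect_identical(length(m), 1L)
  expect_identical(m[[1]]$bands, c(1L, 2L))
  expect_identical(format_feature_spec(m[[1]]), "Re4: pd1(1) + pd2(1)")

  m <- merge_contiguous_bands(list(sp("Re5", 3L), sp("Re5", 4L)))
  expect_identical(length(m), 2L)  # parts 0-0.09 and 0.09-0.18 stay apart

  single <- list(sp("Re9", 5L, 2L))
  expect_identical(merge_contiguous_bands(single)[[1]], single[[1]])

  # different polarity or signal kind never merges
  m <- merge_contiguous_bands(list(sp("Re4", 1L), sp("Re4", 2L, pol = "bottom")))
  expect_identical(length(m), 2L)
  m <- merge_contiguous_bands(list(sp("Re4", 4L), sp("Re4", 5L), sp("Re4", 6L)))
  expect_identical(m[[1]]$bands, 4:6)
})

test_that("feature values are extracted by polarity-ranked region channels", {
  rm <- list(ReX = c(1, 2, 3))
  M1 <- matrix(0, 6, 3)
  M1[1, ] <- c(0.5, 0.2, -0.1)
  top1 <- nirsgait:::new_feature_spec("ReX", "top", 1L, 1L, "totalHb")
  expect_equal(extract_feature_values(M1, top1, rm), 0.5)
  bot2 <- nirsgait:::new_feature_spec("ReX", "bottom", 1L, 2L, "totalHb")
  expect_equal(extract_feature_values(M1, bot2, rm), mean(c(-0.1, 0.2)))

  # merged specs average the per-band extractions
  M1[2, ] <- c(0.3, 0.1, 0)
  merged <- nirsgait:::new_feature_spec("ReX", "top", c(1L, 2L), c(1L, 1L),
                                        "totalHb")
  expect_equal(extract_feature_values(M1, merged, rm), mean(c(0.5, 0.3)))

  bad <- nirsgait:::new_feature_spec("ReX", "top", 1L, 4L, "totalHb")
  expect_error(extract_feature_values(M1, bad, rm), "key_count")
})

test_that("the ANOVA filter matches the squared-t closed form", {
  g1 <- c(1, 2, 3, 4, 5); g2 <- c(2, 3, 4, 5, 6)
  res <- anova_filter(list(A = g1, B = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  # two-group one-way ANOVA F equals the squared two-sample t: F = 1 here
  expect_equal(unname(res$p_values), tt$p.value)
  expect_equal(tt$statistic[["t"]]^2, 1)
  expect_equal(unname(res$p_values), 1 - pf(1, 1, 8))
  expect_false(res$retained)

  # perfectly separated groups with tiny jitter are retained
  set.seed(71)
  res <- anova_filter(list(A = rnorm(4, 0, 1e-3), B = rnorm(4, 1, 1e-3)))
  expect_true(res$retained)
  expect_lt(min(res$p_values), 1e-6)

  # identical class distributions are not retained; degenerate zero-variance
  # equal-mean groups get p = 1
  v <- c(1, 2, 3)
  expect_false(anova_filter(list(A = v, B = v, C = v))$retained)
  expect_equal(unname(anova_filter(list(A = rep(2, 4),
                                        B = rep(2, 4)))$p_values), 1)

  # retention on ANY significant pair
  res <- anova_filter(list(A = rnorm(5, 0, 0.01), B = rnorm(5, 0, 0.01),
                           C = rnorm(5, 5, 0.01)))
  expect_true(res$retained)
})

test_that("the ANOVA filter holds its size under the permutation null", {
  set.seed(72)
  alpha <- 0.05
  n_rep <- 400L
  vals <- rnorm(20)
  hits <- vapply(seq_len(n_rep), function(i) {
    p <- sample(vals)
    anova_filter(list(A = p[1:10], B = p[11:20]), alpha)$retained
  }, logical(1))
  rate <- mean(hits)
  bound <- qbinom(c(0.005, 0.995), n_rep, alpha) / n_rep
  expect_gte(rate, bound[1])
  expect_lte(rate, bound[2])
})

test_that("null cohorts select no region reproducibly", {
  # with no injected signal, selection statistics are class-symmetric:
  # across reseeded cohorts no (band, region, polarity) cell survives the
  # cascade every time
  keys <- list()
  for (r in 1:5) {
    cfg <- synth_config(n_subjects = 4, signal_kinds = "totalHb",
                        seed = 8800 + r, effect_map = list())
    feats <- cohort_feature_matrices(generate_cohort(cfg))
    sel <- select_features(feats, "walking_speed")
    keys[[r]] <- unique(vapply(sel$specs, function(s)
      paste(s$region, s$polarity, paste(s$bands, collapse = ",")),
      character(1)))
  }
  always <- Reduce(intersect, keys)
  expect_identical(length(always), 0L)
})

test_that("stronger injected effects are selected at least as often", {
  levels <- c(0.01, 0.03, 0.08)
  n_rep <- 20L
  freq <- numeric(length(levels))
  target_regions <- c("Re19", "Re20", "Re21")  # regions containing ch15
  for (li in seq_along(levels)) {
    hits <- 0L
    for (r in seq_len(n_rep)) {
      d <- levels[li]
      cfg <- synth_config(n_subjects = 4, signal_kinds = "totalHb",
                          seed = 7000 + 100 * li + r,
                          effect_map = list(effect_spec(2, 15, "totalHb",
                                                        c(LD = -d, MD = 0,
                                                          HD = d))))
      feats <- cohort_feature_matrices(generate_cohort(cfg))
      sel <- select_features(feats, "walking_speed")
      hit <- any(vapply(sel$specs, function(s)
        s$region %in% target_regions && 2L %in% s$bands, logical(1)))
      hits <- hits + hit
    }
    freq[li] <- hits / n_rep
  }
  expect_true(all(diff(freq) >= 0))
  expect_gt(freq[length(levels)], freq[1])
})
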