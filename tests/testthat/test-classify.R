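test_that("adaptive probabilities interpolate between the critical values", {
  p <- ga_params(pc1 = 0.9, pc2 = 0.6, pm1 = 0.1, pm2 = 0.01)

  st <- list(f_max = 1.0, f_avg = 0.5, f_prime = 0.75, f = 0.75)
  expect_equal(adaptive_probabilities(st, p)[["pc"]], 0.75)

  st$f_prime <- 0.5                       # at the branch point
  expect_equal(adaptive_probabilities(st, p)[["pc"]], 0.9)
  st$f_prime <- 1.0                       # at the population maximum
  expect_equal(adaptive_probabilities(st, p)[["pc"]], 0.6)
  st$f_prime <- 0.2                       # below average
  expect_equal(adaptive_probabilities(st, p)[["pc"]], 0.9)

  # converged population: upper critical values
  st <- list(f_max = 0.7, f_avg = 0.7, f_prime = 0.7, f = 0.7)
  expect_equal(unname(adaptive_probabilities(st, p)), c(0.9, 0.1))

  # outputs always within the critical bounds
  set.seed(81)
  for (i in 1:50) {
    fa <- runif(1); fm <- fa + runif(1) * (1 - fa)
    st <- list(f_max = fm, f_avg = fa, f_prime = runif(1), f = runif(1))
    pr <- adaptive_probabilities(st, p)
    expect_gte(pr[["pc"]], 0.6); expect_lte(pr[["pc"]], 0.9)
    expect_gte(pr[["pm"]], 0.01); expect_lte(pr[["pm"]], 0.1)
  }
  expect_error(adaptive_probabilities(list(f_max = 0.4, f_avg = 0.5,
                                           f_prime = 0.4, f = 0.4), p),
               "f_max")
})

test_that("LOSO fitness is 1 for separable features and exact on duplicates", {
  subjects <- rep(sprintf("S%02d", 1:6), each = 6)
  states <- rep(gait_states(), 6)
  labels <- state_class(states, "walking_speed")
  class_idx <- as.numeric(factor(labels, levels = c("LD", "MD", "HD")))

  X <- cbind(class_idx)
  expect_equal(loso_fitness(TRUE, X, subjects, labels), 1.0)

  # duplicating the feature set leaves the RBF kernel (gamma = 1/d)
  # unchanged, so the fitness is identical
  X2 <- cbind(class_idx, class_idx)
  set.seed(82)
  Xn <- cbind(class_idx + rnorm(36, 0, 0.8))
  f1 <- loso_fitness(TRUE, Xn, subjects, labels)
  f2 <- loso_fitness(c(TRUE, TRUE), cbind(Xn, Xn), subjects, labels)
  expect_equal(f1, f2)
  expect_lt(abs(f2 - f1), 0.02)

  expect_error(loso_fitness(FALSE, X, subjects, labels), "empty")
})

test_that("LOSO fitness sits at chance for uninformative permuted labels", {
  set.seed(83)
  subjects <- rep(sprintf("S%02d", 1:6), each = 6)
  labels0 <- rep(rep(c("A", "B", "C"), each = 2), 6)  # balanced per subject
  # permute labels within subject (keeps every training fold balanced) and
  # draw fresh uninformative features each round
  accs <- replicate(50, {
    X <- matrix(rnorm(36 * 2), 36, 2)
    labs <- unlist(lapply(split(labels0, subjects), sample), use.names = FALSE)
    loso_fitness(c(TRUE, TRUE), X, subjects, labs)
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.06)
})

test_that("the GA finds the optimum of a 10-bit problem (exhaustive oracle)", {
  target <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  fitness <- function(mask) sum(mask == target) / 10

  # exhaustive search over all 1024 masks
  best_brute <- -1
  for (i in 0:1023) {
    mask <- as.logical(bitwAnd(bitwShiftR(i, 0:9), 1L))
    if (any(mask)) best_brute <- max(best_brute, fitness(mask))
  }
  expect_equal(best_brute, 1.0)

  res <- ga_select(10, fitness,
                   ga_params(population_size = 20, n_iterations = 600,
                             seed = 4))
  expect_identical(res$mask, target)
  expect_equal(res$fitness, best_brute)

  # determinism: identical seed, identical trace and mask
  res2 <- ga_select(10, fitness,
                    ga_params(population_size = 20, n_iterations = 600,
                              seed = 4))
  expect_identical(res$mask, res2$mask)
  expect_identical(res$trace, res2$trace)

  # elitism: the best-so-far trace never decreases
  expect_true(all(diff(res$trace) >= 0))
})

test_that("a single candidate is returned after one evaluation", {
  res <- ga_select(1, function(mask) 0.42,
                   ga_params(population_size = 4, n_iterations = 10, seed = 1))
  expect_identical(res$mask, TRUE)
  expect_equal(res$fitness, 0.42)
})

test_that("ga_params validates its critical values", {
  expect_error(ga_params(pc1 = 0.5, pc2 = 0.6), "pc")
  expect_error(ga_params(pm1 = 0.01, pm2 = 0.1), "pm")
  expect_error(ga_params(population_size = 1), "population")
})

test_that("train/test evaluation scores 11 x 6 = 66 instances", {
  mk_features <- function(subjects, jitter_sd = 0.05, seed = 1) {
    set.seed(seed)
    feats <- list()
    for (sub in subjects) {
      for (st in gait_states()) {
        M <- matrix(rnorm(132, 0, 0.01), 6, 22)
        cls <- state_class(st, "walking_speed")
        # positive, ordered class levels: visible to "top"-polarity extraction
        M[3, 7] <- c(LD = 1, MD = 2, HD = 3)[[cls]] + rnorm(1, 0, jitter_sd)
        dimnames(M) <- list(paste0("pd", 1:6), paste0("ch", 1:22))
        feats[[sub]][["totalHb"]][[st]] <- M
      }
    }
    feats
  }
  spec <- nirsgait:::new_feature_spec("Re10", "top", 3L, 1L, "totalHb")
  # ch7 is in Re10 = {6, 7, 9}

  train <- mk_features(sprintf("T%02d", 1:5), seed = 2)
  test <- mk_features(sprintf("U%02d", 1:11), seed = 3)
  res <- train_and_test(train, test, list(spec), "walking_speed")
  expect_identical(res$n_total, 66L)
  expect_identical(dim(res$confusion), c(3L, 3L))
  expect_equal(res$accuracy, res$n_correct / 66)
  expect_gt(res$accuracy, 0.9)  # separable synthetic features

  # memorization check: same subjects as training, relabelled ids
  test_same <- mk_features(sprintf("V%02d", 1:5), seed = 2)
  res2 <- train_and_test(train, test_same, list(spec), "walking_speed")
  expect_equal(res2$accuracy, 1.0)

  expect_error(train_and_test(train, train, list(spec), "walking_speed"),
               "overlap")
})

test_that("uninformative features fall to the majority-class prior", {
  set.seed(85)
  mk_noise <- function(subjects) {
    feats <- list()
    for (sub in subjects) for (st in gait_states()) {
      M <- matrix(rnorm(132), 6, 22)
      dimnames(M) <- list(paste0("pd", 1:6), paste0("ch", 1:22))
      feats[[sub]][["totalHb"]][[st]] <- M
    }
    feats
  }
  spec <- nirsgait:::new_feature_spec("Re10", "top", 3L, 1L, "totalHb")
  res <- train_and_test(mk_noise(sprintf("T%02d", 1:8)),
                        mk_noise(sprintf("U%02d", 1:11)),
                        list(spec), "walking_speed")
  # MD contains 3 of the 6 states; chance under majority collapse is 1/2
  n <- res$n_total
  bounds <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(res$accuracy, bounds[1])
  expect_lte(res$accuracy, bounds[2])
})
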