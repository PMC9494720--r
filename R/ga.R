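# Adaptive-probability genetic algorithm for feature-subset search. Crossover
# and mutation probabilities shrink linearly for above-average fitness, so
# good chromosomes are protected while poor ones keep exploring.

#' GA parameter set
#'
#' The four critical probabilities follow the classic adaptive scheme;
#' their values are configurable. The iteration budget counts fitness
#' evaluations by default (set \code{budget_unit = "generations"} to count
#' generations instead).
#'
#' @param pc1,pc2 Upper / lower critical crossover probabilities
#'   (\code{pc1 > pc2}, both in (0, 1]).
#' @param pm1,pm2 Upper / lower critical mutation probabilities
#'   (\code{pm1 > pm2}).
#' @param population_size Number of chromosomes per generation.
#' @param n_iterations Search budget (default 20000).
#' @param budget_unit \code{"evaluations"} or \code{"generations"}.
#' @param seed Integer seed for the GA's random stream.
#' @return A list of class \code{"ga_params"}.
#' @export
ga_params <- function(pc1 = 0.9, pc2 = 0.6, pm1 = 0.1, pm2 = 0.01,
                      population_size = 50L, n_iterations = 20000L,
                      budget_unit = c("evaluations", "generations"),
                      seed = 1L) {
  budget_unit <- match.arg(budget_unit)
  if (!(pc1 > pc2 && pc2 > 0 && pc1 <= 1)) {
    stop("need 0 < pc2 < pc1 <= 1", call. = FALSE)
  }
  if (!(pm1 > pm2 && pm2 > 0 && pm1 <= 1)) {
    stop("need 0 < pm2 < pm1 <= 1", call. = FALSE)
  }
  if (population_size < 2L || n_iterations < 1L) {
    stop("invalid population size or iteration budget", call. = FALSE)
  }
  structure(list(pc1 = pc1, pc2 = pc2, pm1 = pm1, pm2 = pm2,
                 population_size = as.integer(population_size),
                 n_iterations = as.integer(n_iterations),
                 budget_unit = budget_unit, seed = as.integer(seed)),
            class = "ga_params")
}

#' Adaptive crossover and mutation probabilities
#'
#' For an individual at or above average fitness, the probabilities decrease
#' linearly from the upper critical value at \code{f = f_avg} to the lower
#' critical value at \code{f = f_max}; below-average individuals use the
#' upper value. When the population has converged (\code{f_max == f_avg})
#' the upper values are used.
#'
#' @param stats List with \code{f_max}, \code{f_avg}, \code{f_prime} (larger
#'   fitness of the crossover pair) and \code{f} (fitness of the mutation
#'   candidate).
#' @param params A \code{\link{ga_params}} object.
#' @return Named numeric vector \code{c(pc = ..., pm = ...)}, always within
#'   \code{[pc2, pc1]} and \code{[pm2, pm1]}.
#' @export
adaptive_probabilities <- function(stats, params) {
  f_max <- stats$f_max; f_avg <- stats$f_avg
  if (f_max < f_avg) stop("f_max must be >= f_avg", call. = FALSE)
  lin <- function(p1, p2, f) {
    if (f_max == f_avg || f < f_avg) return(p1)
    p <- p1 - (p1 - p2) * (f - f_avg) / (f_max - f_avg)
    min(max(p, p2), p1)
  }
  c(pc = lin(params$pc1, params$pc2, stats$f_prime),
    pm = lin(params$pm1, params$pm2, stats$f))
}

#' Genetic-algorithm feature-subset search
#'
#' Generational GA over bitmasks of length \code{n_candidates}:
#' fitness-proportional (roulette) selection, single-point crossover at the
#' adaptive probability pc, per-bit mutation at the adaptive probability pm,
#' elitism of one. Fitness values are cached by mask, so the evaluation
#' budget is spent only on novel chromosomes. Deterministic under a fixed
#' \code{params$seed}.
#'
#' @param n_candidates Number of candidate features (chromosome length).
#' @param fitness_fn Function taking a logical mask, returning a fitness in
#'   [0, 1]. Empty masks are scored 0 without calling \code{fitness_fn}.
#' @param params A \code{\link{ga_params}} object.
#' @return List with \code{mask} (best-ever logical mask), \code{fitness},
#'   \code{trace} (best fitness per generation, non-decreasing),
#'   \code{n_evaluations} (novel fitness evaluations spent).
#' @export
ga_select <- function(n_candidates, fitness_fn, params = ga_params()) {
  stopifnot(inherits(params, "ga_params"))
  n_candidates <- as.integer(n_candidates)
  if (n_candidates < 1L) stop("need at least one candidate", call. = FALSE)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  evaluate <- function(mask) {
    if (!any(mask)) return(0)
    key <- rawToChar(as.raw(44L + mask))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- fitness_fn(mask)
    n_eval <<- n_eval + 1L
    cache[[key]] <- f
    f
  }

  np <- params$population_size
  pop <- lapply(seq_len(np), function(i) stats::runif(n_candidates) < 0.5)
  # the evaluation budget counts chromosome evaluations (generations x
  # population); the cache only avoids recomputing repeated masks
  n_gen <- if (params$budget_unit == "generations") params$n_iterations
           else max(1L, as.integer(ceiling(params$n_iterations / np)))

  best_mask <- NULL; best_fit <- -Inf; trace <- numeric(0)
  gen <- 1L
  repeat {
    fit <- vapply(pop, evaluate, numeric(1))
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_mask <- pop[[which.max(fit)]]
    }
    trace <- c(trace, best_fit)
    if (gen >= n_gen) break

    f_max <- max(fit); f_avg <- mean(fit)
    # roulette selection
    w <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / np, np)
    parents <- sample.int(np, np, replace = TRUE, prob = w)
    nxt <- vector("list", np)
    for (i in seq(1L, np - 1L, by = 2L)) {
      a <- pop[[parents[i]]]; b <- pop[[parents[i + 1L]]]
      f_prime <- max(fit[parents[i]], fit[parents[i + 1L]])
      pc <- adaptive_probabilities(
        list(f_max = f_max, f_avg = f_avg, f_prime = f_prime, f = f_prime),
        params)[["pc"]]
      if (n_candidates > 1L && stats::runif(1) < pc) {
        cut <- sample.int(n_candidates - 1L, 1L)
        tmp <- c(a[seq_len(cut)], b[(cut + 1L):n_candidates])
        b <- c(b[seq_len(cut)], a[(cut + 1L):n_candidates])
        a <- tmp
      }
      nxt[[i]] <- a; nxt[[i + 1L]] <- b
    }
    if (np %% 2L == 1L) nxt[[np]] <- pop[[parents[np]]]
    # adaptive bit-flip mutation (fitness of the pre-mutation parent)
    for (i in seq_len(np)) {
      pm <- adaptive_probabilities(
        list(f_max = f_max, f_avg = f_avg, f_prime = fit[parents[i]],
             f = fit[parents[i]]), params)[["pm"]]
      flip <- stats::runif(n_candidates) < pm
      nxt[[i]] <- xor(nxt[[i]], flip)
    }
    # elitism: best-ever chromosome replaces the first slot
    nxt[[1L]] <- best_mask
    pop <- nxt
    gen <- gen + 1L
  }
  list(mask = best_mask, fitness = best_fit, trace = trace,
       n_evaluations = n_eval)
}
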