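#' Fitness context for binary feature selection
#'
#' Wraps an objective over binary masks so every selector shares one
#' interface.  `evaluate` must accept a 0/1 vector of length `dimension`
#' and return a single finite fitness (larger is better); it must be
#' deterministic for a given mask.
#'
#' @param evaluate Function `mask -> numeric(1)`.
#' @param dimension Number of features (mask length).
#' @return A `fitness_context`.
#' @seealso [wrapper_fitness()] for the classifier-accuracy objective.
#' @export
fitness_context <- function(evaluate, dimension) {
  stopifnot(is.function(evaluate), dimension >= 1)
  structure(list(evaluate = evaluate, dimension = as.integer(dimension)),
            class = "fitness_context")
}

#' Wrapper fitness: cross-validated classifier accuracy
#'
#' The wrapper objective scored by every selector: restrict the feature
#' table to the masked columns, run stratified k-fold CV with the given
#' classifier, and return the pooled accuracy (percent).  The fold
#' partition is fixed by `seed` and the classifier's initialisation seed
#' is derived from the mask, so the objective is deterministic per mask.
#' Evaluations are cached, as selectors revisit masks.
#'
#' @param features A [feature_table()].
#' @param spec A [classifier_spec()] (default KNN, k = 3).
#' @param folds CV folds for the fitness (default 10; small values such
#'   as 2-3 make wrapper search far cheaper at little ranking cost).
#' @param seed Partition seed.
#' @param positive Positive class, default `"focal"`.
#' @return A [fitness_context()] over the feature columns.
#' @export
wrapper_fitness <- function(features, spec = classifier_spec("knn"),
                            folds = 10, seed = 1, positive = "focal") {
  cols <- feature_columns(features)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(mask) {
    mask <- as.integer(mask != 0)
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    sub <- apply_mask(features, mask)
    sp <- spec
    sp$seed <- spec$seed + (sum(mask * seq_along(mask)) %% 9973L)
    acc <- cross_validate(sub, sp, folds = folds, seed = seed,
                          positive = positive)$metrics$acc
    cache[[key]] <- acc
    acc
  }
  fitness_context(evaluate, length(cols))
}

#' Sigmoid binarization
#'
#' The transfer step shared by the velocity/position based selectors:
#' `S(v) = 1 / (1 + exp(-v))`, and the bit is set when the uniform draw
#' `rho` does not exceed `S(v)`.
#'
#' @param v Real value(s).
#' @param rho Uniform draws in `[0, 1]`, same length as `v` (defaults to
#'   fresh draws).
#' @return Integer 0/1 vector.
#' @export
sigmoid_binarize <- function(v, rho = stats::runif(length(v))) {
  as.integer(rho <= 1 / (1 + exp(-v)))
}

# improvement comparator: larger fitness wins; ties prefer fewer features
is_better <- function(f_new, n_new, f_old, n_old) {
  (f_new > f_old) || (f_new == f_old && n_new < n_old)
}

repair_mask <- function(bits) {
  if (sum(bits) == 0L) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}

init_population <- function(pop, d) {
  m <- matrix(stats::rbinom(pop * d, 1L, 0.5), pop, d)
  t(apply(m, 1, repair_mask))
}

new_selection_result <- function(method, mask, best_fitness, history,
                                 seed, n_evals, config, feature_names = NULL) {
  structure(list(method = method,
                 mask = as.integer(mask),
                 best_fitness = best_fitness,
                 history = history,
                 n_selected = sum(mask != 0),
                 seed = seed,
                 n_evals = n_evals,
                 config = config,
                 feature_names = feature_names,
                 selected = if (!is.null(feature_names)) feature_names[mask != 0]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d/%d features, best fitness %.4g (%d evaluations)\n",
              toupper(x$method), x$n_selected, length(x$mask),
              x$best_fitness, x$n_evals))
  invisible(x)
}

# shared bookkeeping: closes over best-so-far state
make_tracker <- function() {
  env <- new.env(parent = emptyenv())
  env$best_f <- -Inf
  env$best_mask <- NULL
  env$history <- numeric(0)
  env$n_evals <- 0L
  env$offer <- function(mask, f) {
    env$n_evals <- env$n_evals + 1L
    if (is.null(env$best_mask) ||
        is_better(f, sum(mask), env$best_f, sum(env$best_mask))) {
      env$best_f <- f
      env$best_mask <- mask
    }
    f
  }
  env$tick <- function() env$history <- c(env$history, env$best_f)
  env
}

#' Binary bat algorithm selector
#'
#' Echolocation-inspired search: each bat carries a continuous velocity
#' updated toward the global best with a random frequency draw, optionally
#' perturbed by a loudness-scaled local walk, then binarized through the
#' sigmoid transfer.  A candidate replaces the bat's position with
#' probability given by its loudness and only on improvement; loudness and
#' pulse rate follow their geometric schedules (with `alpha = gamma = 1`,
#' the printed configuration, loudness stays constant).
#'
#' @param ctx A [fitness_context()].
#' @param population Number of bats (default 4).
#' @param iterations Iterations (default 40).
#' @param loudness Initial loudness A0 (default 1).
#' @param pulse_rate Base pulse rate r0 (default 0.5).
#' @param alpha,gamma Loudness decay and pulse-rate growth constants
#'   (default 1, the stated configuration, making both schedules flat).
#' @param f_min,f_max Frequency bounds (defaults 0 and 2).
#' @param seed RNG seed.
#' @return A `selection_result`.
#' @export
select_bba <- function(ctx, population = 4, iterations = 40, loudness = 1,
                       pulse_rate = 0.5, alpha = 1, gamma = 1,
                       f_min = 0, f_max = 2, seed = 1) {
  stopifnot(inherits(ctx, "fitness_context"))
  if (population < 2 || iterations < 1) {
    stop("config error: population >= 2 and iterations >= 1 required", call. = FALSE)
  }
  d <- ctx$dimension
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  tr <- make_tracker()
  B <- init_population(population, d)
  V <- matrix(0, population, d)
  f <- apply(B, 1, function(b) tr$offer(b, ctx$evaluate(b)))
  A <- rep(loudness, population)
  tr$tick()
  for (t in seq_len(iterations)) {
    r_t <- pulse_rate * (1 - exp(-gamma * t))
    for (i in seq_len(population)) {
      freq <- f_min + (f_min - f_max) * stats::runif(1)
      V[i, ] <- V[i, ] + (B[i, ] - tr$best_mask) * freq
      v_use <- V[i, ]
      if (stats::runif(1) > r_t) {
        v_use <- v_use + stats::runif(d, -1, 1) * mean(A)   # local walk
      }
      cand <- repair_mask(sigmoid_binarize(v_use))
      fc <- tr$offer(cand, ctx$evaluate(cand))
      if (stats::runif(1) < A[i] && is_better(fc, sum(cand), f[i], sum(B[i, ]))) {
        B[i, ] <- cand
        f[i] <- fc
        A[i] <- alpha * A[i]
      }
    }
    tr$tick()
  }
  new_selection_result("bba", tr$best_mask, tr$best_f, tr$history, seed, tr$n_evals,
                       list(population = population, iterations = iterations,
                            loudness = loudness, pulse_rate = pulse_rate,
                            alpha = alpha, gamma = gamma,
                            f_min = f_min, f_max = f_max))
}

#' Binary differential evolution selector
#'
#' For each target vector, three distinct donors are drawn; the difference
#' vector is 0 where the first two donors agree and the first donor's bit
#' elsewhere, the mutant takes a 1 where the difference vector is 1 and
#' the third donor's bit otherwise, and binomial crossover with rate `CR`
#' (plus one forced coordinate) forms the trial, which replaces the parent
#' only on improvement.
#'
#' @param ctx A [fitness_context()].
#' @param population Number of vectors (default 10, must be >= 4).
#' @param iterations Generations (default 100).
#' @param CR Crossover rate in `[0, 1]` (default 0.9).
#' @param seed RNG seed.
#' @return A `selection_result`.
#' @export
select_bde <- function(ctx, population = 10, iterations = 100, CR = 0.9, seed = 1) {
  stopifnot(inherits(ctx, "fitness_context"))
  if (population < 4) {
    stop("config error: BDE needs population >= 4 (three donors distinct from the target)",
         call. = FALSE)
  }
  d <- ctx$dimension
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  tr <- make_tracker()
  X <- init_population(population, d)
  f <- apply(X, 1, function(b) tr$offer(b, ctx$evaluate(b)))
  tr$tick()
  for (t in seq_len(iterations)) {
    for (i in seq_len(population)) {
      donors <- sample(setdiff(seq_len(population), i), 3L)
      mutant <- bde_mutant(X[donors[1L], ], X[donors[2L], ], X[donors[3L], ])
      trial <- bde_crossover(X[i, ], mutant, CR)
      trial <- repair_mask(trial)
      ft <- tr$offer(trial, ctx$evaluate(trial))
      if (is_better(ft, sum(trial), f[i], sum(X[i, ]))) {
        X[i, ] <- trial
        f[i] <- ft
      }
    }
    tr$tick()
  }
  new_selection_result("bde", tr$best_mask, tr$best_f, tr$history, seed, tr$n_evals,
                       list(population = population, iterations = iterations, CR = CR))
}

bde_mutant <- function(x_r1, x_r2, x_r3) {
  diffv <- ifelse(x_r1 == x_r2, 0L, x_r1)
  as.integer(ifelse(diffv == 1L, 1L, x_r3))
}

bde_crossover <- function(parent, mutant, CR) {
  d <- length(parent)
  take <- stats::runif(d) <= CR
  take[sample.int(d, 1L)] <- TRUE      # forced coordinate from the mutant
  as.integer(ifelse(take, mutant, parent))
}

#' Binary firefly algorithm selector
#'
#' Every firefly moves toward each brighter one with attractiveness
#' `beta0 * exp(-gamma * r^2)` (Cartesian distance `r`; with the stated
#' `gamma = 0` the attraction is distance-independent) plus a zero-mean
#' random term `alpha * (U[0,1] - 1/2)`, in a continuous position space
#' that is re-binarized through the sigmoid each iteration.
#'
#' @param ctx A [fitness_context()].
#' @param population Number of fireflies (default 6).
#' @param iterations Iterations (default 100).
#' @param alpha Randomisation weight (default 0.5).
#' @param gamma Light absorption coefficient (default 0).
#' @param beta0 Attractiveness at distance zero (default 1).
#' @param seed RNG seed.
#' @return A `selection_result`.
#' @export
select_fa <- function(ctx, population = 6, iterations = 100, alpha = 0.5,
                      gamma = 0, beta0 = 1, seed = 1) {
  stopifnot(inherits(ctx, "fitness_context"))
  if (population < 2) stop("config error: population >= 2 required", call. = FALSE)
  d <- ctx$dimension
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  tr <- make_tracker()
  B <- init_population(population, d)
  Xc <- B + 0.0                        # continuous positions
  f <- apply(B, 1, function(b) tr$offer(b, ctx$evaluate(b)))
  tr$tick()
  for (t in seq_len(iterations)) {
    for (i in seq_len(population)) {
      moved <- FALSE
      for (j in seq_len(population)) {
        if (f[j] > f[i]) {
          r2 <- sum((Xc[i, ] - Xc[j, ])^2)
          batt <- fa_attractiveness(sqrt(r2), beta0, gamma)
          Xc[i, ] <- Xc[i, ] + batt * (Xc[j, ] - Xc[i, ]) +
            alpha * (stats::runif(d) - 0.5)
          moved <- TRUE
        }
      }
      if (!moved) {                     # brightest firefly wanders randomly
        Xc[i, ] <- Xc[i, ] + alpha * (stats::runif(d) - 0.5)
      }
      cand <- repair_mask(sigmoid_binarize(Xc[i, ]))
      B[i, ] <- cand
      f[i] <- tr$offer(cand, ctx$evaluate(cand))
    }
    tr$tick()
  }
  new_selection_result("fa", tr$best_mask, tr$best_f, tr$history, seed, tr$n_evals,
                       list(population = population, iterations = iterations,
                            alpha = alpha, gamma = gamma, beta0 = beta0))
}

fa_attractiveness <- function(r, beta0 = 1, gamma = 0) beta0 * exp(-gamma * r^2)

#' Genetic algorithm selector
#'
#' Fitness-proportional (roulette) parent selection, single-point
#' crossover applied with probability `CR`, per-bit mutation with
#' probability `MR`, and elitism of the best chromosome each generation.
#'
#' @param ctx A [fitness_context()].
#' @param population Number of chromosomes (default 10).
#' @param iterations Generations (default 100).
#' @param CR Crossover probability (default 0.8).
#' @param MR Per-bit mutation probability (default 0.01).
#' @param seed RNG seed.
#' @return A `selection_result`.
#' @export
select_ga <- function(ctx, population = 10, iterations = 100, CR = 0.8,
                      MR = 0.01, seed = 1) {
  stopifnot(inherits(ctx, "fitness_context"))
  if (population < 2) stop("config error: population >= 2 required", call. = FALSE)
  d <- ctx$dimension
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  tr <- make_tracker()
  X <- init_population(population, d)
  f <- apply(X, 1, function(b) tr$offer(b, ctx$evaluate(b)))
  tr$tick()
  for (t in seq_len(iterations)) {
    new_X <- matrix(0L, population, d)
    new_f <- numeric(population)
    new_X[1L, ] <- tr$best_mask        # elitism
    new_f[1L] <- tr$best_f
    i <- 2L
    while (i <= population) {
      parents <- roulette_pick(f, 2L)
      c1 <- X[parents[1L], ]
      c2 <- X[parents[2L], ]
      if (stats::runif(1) < CR && d >= 2L) {
        cut <- sample.int(d - 1L, 1L)
        kids <- ga_crossover(c1, c2, cut)
        c1 <- kids[[1L]]
        c2 <- kids[[2L]]
      }
      for (kid in list(c1, c2)) {
        if (i > population) break
        flip <- stats::runif(d) < MR
        kid <- as.integer(xor(kid, flip))
        kid <- repair_mask(kid)
        new_X[i, ] <- kid
        new_f[i] <- tr$offer(kid, ctx$evaluate(kid))
        i <- i + 1L
      }
    }
    X <- new_X
    f <- new_f
    tr$tick()
  }
  new_selection_result("ga", tr$best_mask, tr$best_f, tr$history, seed, tr$n_evals,
                       list(population = population, iterations = iterations,
                            CR = CR, MR = MR))
}

ga_crossover <- function(p1, p2, cut) {
  d <- length(p1)
  list(as.integer(c(p1[seq_len(cut)], p2[(cut + 1L):d])),
       as.integer(c(p2[seq_len(cut)], p1[(cut + 1L):d])))
}

roulette_pick <- function(f, n) {
  w <- f - min(f)
  if (sum(w) <= 0) w <- rep(1, length(f))
  sample.int(length(f), n, replace = TRUE, prob = w + 1e-12)
}

#' Binary grey wolf optimizer selector
#'
#' The three best wolves (alpha, beta, delta) guide every other wolf: per
#' dimension, each leader proposes a position through the encircling
#' update with coefficient `A` drawn from a window shrinking linearly from
#' 2 to 0, and the candidate is the mean of the three proposals, mapped to
#' a bit through the steep transfer `T(x) = 1 / (1 + exp(-10 (x - 0.5)))`
#' compared against a uniform draw.
#'
#' @param ctx A [fitness_context()].
#' @param population Number of wolves (default 10, must be >= 3).
#' @param iterations Iterations (default 100).
#' @param seed RNG seed.
#' @return A `selection_result`.
#' @export
select_gwo <- function(ctx, population = 10, iterations = 100, seed = 1) {
  stopifnot(inherits(ctx, "fitness_context"))
  if (population < 3) {
    stop("config error: GWO needs population >= 3 (alpha, beta, delta leaders)",
         call. = FALSE)
  }
  d <- ctx$dimension
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  tr <- make_tracker()
  X <- init_population(population, d)
  f <- apply(X, 1, function(b) tr$offer(b, ctx$evaluate(b)))
  tr$tick()
  for (t in seq_len(iterations)) {
    a <- 2 * (1 - t / iterations)
    ord <- order(f, decreasing = TRUE)
    leaders <- X[ord[1:3], , drop = FALSE]
    for (i in seq_len(population)) {
      guided <- matrix(0, 3L, d)
      for (l in 1:3) {
        A <- 2 * a * stats::runif(d) - a
        C <- 2 * stats::runif(d)
        D <- abs(C * leaders[l, ] - X[i, ])
        guided[l, ] <- leaders[l, ] - A * D
      }
      y <- colMeans(guided)
      bit_prob <- gwo_transfer(y)
      cand <- repair_mask(as.integer(stats::runif(d) <= bit_prob))
      X[i, ] <- cand
      f[i] <- tr$offer(cand, ctx$evaluate(cand))
    }
    tr$tick()
  }
  new_selection_result("gwo", tr$best_mask, tr$best_f, tr$history, seed, tr$n_evals,
                       list(population = population, iterations = iterations))
}

gwo_transfer <- function(x) 1 / (1 + exp(-10 * (x - 0.5)))

#' Binary particle swarm optimization selector
#'
#' Velocities are updated with inertia annealed linearly from `w_max` to
#' `w_min`, cognitive attraction to the particle's personal best and
#' social attraction to the global best (factors `c1`, `c2`), clamped to
#' `[-v_max, v_max]`, and positions are re-drawn through the sigmoid
#' transfer each iteration.
#'
#' @param ctx A [fitness_context()].
#' @param population Number of particles (default 10).
#' @param iterations Iterations (default 100).
#' @param c1,c2 Cognitive and social factors (default 2 each).
#' @param w_min,w_max Inertia bounds (defaults 0.4 and 0.9).
#' @param v_max Velocity clamp (default 6).
#' @param seed RNG seed.
#' @return A `selection_result`.
#' @export
select_pso <- function(ctx, population = 10, iterations = 100, c1 = 2, c2 = 2,
                       w_min = 0.4, w_max = 0.9, v_max = 6, seed = 1) {
  stopifnot(inherits(ctx, "fitness_context"))
  if (population < 2) stop("config error: population >= 2 required", call. = FALSE)
  d <- ctx$dimension
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  tr <- make_tracker()
  X <- init_population(population, d)
  V <- matrix(0, population, d)
  f <- apply(X, 1, function(b) tr$offer(b, ctx$evaluate(b)))
  pbest <- X
  pf <- f
  tr$tick()
  for (t in seq_len(iterations)) {
    w <- w_max - (w_max - w_min) * t / iterations
    for (i in seq_len(population)) {
      V[i, ] <- w * V[i, ] +
        c1 * stats::runif(d) * (pbest[i, ] - X[i, ]) +
        c2 * stats::runif(d) * (tr$best_mask - X[i, ])
      V[i, ] <- pmin(pmax(V[i, ], -v_max), v_max)
      cand <- repair_mask(sigmoid_binarize(V[i, ]))
      X[i, ] <- cand
      f[i] <- tr$offer(cand, ctx$evaluate(cand))
      if (is_better(f[i], sum(cand), pf[i], sum(pbest[i, ]))) {
        pbest[i, ] <- cand
        pf[i] <- f[i]
      }
    }
    tr$tick()
  }
  new_selection_result("pso", tr$best_mask, tr$best_f, tr$history, seed, tr$n_evals,
                       list(population = population, iterations = iterations,
                            c1 = c1, c2 = c2, w_min = w_min, w_max = w_max,
                            v_max = v_max))
}

#' Exhaustive search over all non-empty masks
#'
#' Validation oracle: evaluates every non-empty mask and returns the
#' global optimum.  Ties are broken toward fewer selected features, then
#' the lexicographically smallest mask.  Refuses dimensions above 20.
#'
#' @param ctx A [fitness_context()] with `dimension <= 20`.
#' @return A `selection_result` (history is the running best over the
#'   enumeration).
#' @export
exhaustive_search <- function(ctx) {
  stopifnot(inherits(ctx, "fitness_context"))
  d <- ctx$dimension
  if (d > 20L) {
    stop("exhaustive search refused for dimension ", d, " (> 20)", call. = FALSE)
  }
  best_mask <- NULL
  best_f <- -Inf
  history <- numeric(0)
  for (m in seq_len(2^d - 1L)) {
    bits <- as.integer(bitwAnd(bitwShiftR(m, 0:(d - 1L)), 1L))
    f <- ctx$evaluate(bits)
    replace <- if (is.null(best_mask)) TRUE
      else if (f != best_f) f > best_f
      else if (sum(bits) != sum(best_mask)) sum(bits) < sum(best_mask)
      else lex_less(bits, best_mask)
    if (replace) {
      best_f <- f
      best_mask <- bits
    }
    history <- c(history, best_f)
  }
  new_selection_result("exhaustive", best_mask, best_f, history,
                       seed = NA_integer_, n_evals = 2L^d - 1L, config = list())
}

lex_less <- function(a, b) {
  i <- which(a != b)
  length(i) > 0L && a[i[1L]] < b[i[1L]]
}

#' Select features with a binary metaheuristic
#'
#' High-level interface: builds the classifier-accuracy wrapper objective
#' over a feature table and runs the chosen selector.
#'
#' @param features A [feature_table()].
#' @param method One of `"bba"`, `"bde"`, `"fa"`, `"ga"`, `"gwo"`,
#'   `"pso"`.
#' @param spec Classifier scoring candidate subsets
#'   ([classifier_spec()]; default KNN, k = 3).
#' @param folds CV folds inside the wrapper fitness (default 10).
#' @param seed Seed for both the fitness partition and the selector.
#' @param positive Positive class, default `"focal"`.
#' @param ... Method-specific arguments forwarded to the `select_*`
#'   function (e.g. `population`, `iterations`).
#' @return A `selection_result` carrying the selected feature names.
#' @export
select_features <- function(features,
                            method = c("pso", "bba", "bde", "fa", "ga", "gwo"),
                            spec = classifier_spec("knn"), folds = 10,
                            seed = 1, positive = "focal", ...) {
  method <- match.arg(method)
  ctx <- wrapper_fitness(features, spec = spec, folds = folds, seed = seed,
                         positive = positive)
  fun <- switch(method, bba = select_bba, bde = select_bde, fa = select_fa,
                ga = select_ga, gwo = select_gwo, pso = select_pso)
  res <- fun(ctx, seed = seed, ...)
  res$feature_names <- feature_columns(features)
  res$selected <- res$feature_names[res$mask != 0]
  res
}
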