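count_first3 <- fitness_context(function(m) sum(m[1:3]), 8)

all_selectors <- list(bba = select_bba, bde = select_bde, fa = select_fa,
                      ga = select_ga, gwo = select_gwo, pso = select_pso)

test_that("sigmoid binarization follows the transfer probability", {
  expect_identical(sigmoid_binarize(0, rho = 0.4), 1L)   # S(0) = 0.5
  expect_identical(sigmoid_binarize(0, rho = 0.6), 0L)
  expect_identical(sigmoid_binarize(20, rho = 1 - 1e-7), 1L)
  set.seed(14)
  rate <- mean(sigmoid_binarize(rep(1, 1e5)))
  expect_lt(abs(rate - 1 / (1 + exp(-1))), 0.005)
})

test_that("binary DE operators match their definitions", {
  x <- c(1L, 0L, 1L, 0L)
  # agreeing donors: mutant is the third donor exactly
  expect_identical(eegfocus:::bde_mutant(x, x, c(0L, 1L, 1L, 0L)), c(0L, 1L, 1L, 0L))
  # difference bit forces a 1
  expect_identical(eegfocus:::bde_mutant(c(1L, 1L, 0L, 0L), c(0L, 1L, 0L, 0L),
                                         c(0L, 0L, 0L, 0L)),
                   c(1L, 0L, 0L, 0L))
  # CR = 1: trial equals the mutant everywhere
  set.seed(15)
  expect_identical(eegfocus:::bde_crossover(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L), 1),
                   c(1L, 1L, 1L, 1L))
  expect_error(select_bde(count_first3, population = 3), "population >= 4")
})

test_that("GA single-point crossover and selector constraints behave", {
  kids <- eegfocus:::ga_crossover(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L), 2L)
  expect_identical(kids[[1]], c(1L, 1L, 0L, 0L))
  expect_identical(kids[[2]], c(0L, 0L, 1L, 1L))
})

test_that("firefly attractiveness and GWO transfer hit their anchors", {
  expect_equal(eegfocus:::fa_attractiveness(0, beta0 = 0.7, gamma = 2), 0.7)
  r <- c(0, 1, 5)
  expect_equal(eegfocus:::fa_attractiveness(r, beta0 = 1, gamma = 0), rep(1, 3))
  expect_equal(eegfocus:::gwo_transfer(0.5), 0.5)
  expect_error(select_gwo(count_first3, population = 2), "population >= 3")
})

test_that("every selector is seed-reproducible with a non-decreasing history", {
  for (nm in names(all_selectors)) {
    fun <- all_selectors[[nm]]
    a <- fun(count_first3, iterations = 10, seed = 3)
    b <- fun(count_first3, iterations = 10, seed = 3)
    expect_identical(a$mask, b$mask, label = nm)
    expect_identical(a$history, b$history, label = nm)
    expect_true(all(diff(a$history) >= 0), label = paste(nm, "history"))
    expect_equal(a$n_selected, sum(a$mask), label = nm)
    expect_gte(a$n_selected, 1)
  }
})

test_that("selectors never return an empty mask even when emptiness pays", {
  penalise <- fitness_context(function(m) -sum(m), 6)
  for (nm in names(all_selectors)) {
    res <- all_selectors[[nm]](penalise, iterations = 10, seed = 4)
    expect_gte(sum(res$mask), 1)
    expect_lte(res$best_fitness, -1)   # an empty mask (fitness 0) is impossible
  }
})

test_that("selectors beat the random-mask floor on a counting landscape", {
  set.seed(16)
  rand_fit <- mean(replicate(1000, sum(rbinom(8, 1, 0.5)[1:3])))
  for (nm in names(all_selectors)) {
    res <- all_selectors[[nm]](count_first3, seed = 5)
    expect_gte(res$best_fitness, rand_fit, label = nm)
  }
})

test_that("exhaustive search finds global optima with the stated tie-breaks", {
  pop <- fitness_context(function(m) sum(m), 3)
  expect_identical(exhaustive_search(pop)$mask, c(1L, 1L, 1L))
  point <- fitness_context(function(m) as.numeric(all(m == c(0, 1, 0))), 3)
  expect_identical(exhaustive_search(point)$mask, c(0L, 1L, 0L))
  # tie-break: fewest features, then lexicographically smallest
  flat <- fitness_context(function(m) 1, 3)
  expect_identical(exhaustive_search(flat)$mask, c(0L, 0L, 1L))
  expect_error(exhaustive_search(fitness_context(function(m) 0, 21)), "refused")
})

test_that("exhaustive search agrees with an independent enumeration", {
  set.seed(17)
  d <- 8
  grid <- as.matrix(expand.grid(rep(list(0:1), d)))
  for (rep_i in 1:25) {
    tab <- stats::runif(2^d)
    fit <- function(m) tab[sum(m * 2^(seq_along(m) - 1)) + 1]
    got <- exhaustive_search(fitness_context(fit, d))
    # second, independently structured enumeration over the full grid
    vals <- apply(grid, 1, fit)
    vals[rowSums(grid) == 0] <- -Inf
    expect_equal(got$best_fitness, max(vals))
    expect_equal(fit(got$mask), max(vals))
  }
})

test_that("the wrapper fitness is deterministic and mask-sensitive", {
  ctx <- wrapper_fitness(small_features, classifier_spec("knn"), folds = 2, seed = 9)
  m <- rep(1L, ctx$dimension)
  expect_identical(ctx$evaluate(m), ctx$evaluate(m))
  expect_true(is.finite(ctx$evaluate(m)))
  expect_gte(ctx$evaluate(m), 0)
  expect_lte(ctx$evaluate(m), 100)
})

test_that("select_features attaches feature names to the chosen mask", {
  res <- select_features(small_features, method = "pso",
                         spec = classifier_spec("knn"), folds = 2, seed = 2,
                         iterations = 5, population = 4)
  expect_s3_class(res, "selection_result")
  expect_identical(res$selected, res$feature_names[res$mask == 1])
  expect_true(all(res$selected %in% names(small_features)))
  td <- generics::tidy(res)
  expect_equal(nrow(td), length(res$mask))
  expect_equal(sum(td$selected), res$n_selected)
  gl <- generics::glance(res)
  expect_equal(gl$n_selected, res$n_selected)
})
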