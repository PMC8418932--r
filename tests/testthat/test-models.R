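test_that("1-NN memorizes distinct training points", {
  set.seed(18)
  x <- matrix(rnorm(40), ncol = 2)
  y <- rep(c("focal", "nonfocal"), 10)
  m <- fit_classifier(classifier_spec("knn", k = 1), x, y)
  expect_identical(as.character(predict(m, x)), y)
})

test_that("KNN uses the city-block metric", {
  x <- rbind(c(0, 0), c(0, 1), c(5, 5))
  y <- c("focal", "focal", "nonfocal")
  m <- fit_classifier(classifier_spec("knn", k = 3), x, y)
  expect_identical(as.character(predict(m, rbind(c(0, 0.4)))), "focal")
  # under L1, (0, 3) is distance 3 from both focal points and 7 from the
  # nonfocal one: still focal
  expect_identical(as.character(predict(m, rbind(c(0, 3)))), "focal")
})

test_that("KNN predictions are invariant to a consistent column permutation", {
  set.seed(19)
  x <- matrix(rnorm(60), ncol = 3)
  y <- rep(c("focal", "nonfocal"), 10)
  q <- matrix(rnorm(15), ncol = 3)
  m1 <- fit_classifier(classifier_spec("knn", k = 3), x, y)
  perm <- c(3, 1, 2)
  m2 <- fit_classifier(classifier_spec("knn", k = 3), x[, perm], y)
  expect_identical(predict(m1, q), predict(m2, q[, perm]))
})

test_that("GRNN predicts its own training points with one point per class", {
  x <- rbind(c(0, 0), c(4, 4))
  y <- c("focal", "nonfocal")
  m <- fit_classifier(classifier_spec("grnn", spread = 1), x, y)
  expect_identical(as.character(predict(m, x)), y)
})

test_that("the RBF SVM separates well-separated blobs at grid sigmas", {
  bf <- blob_features(n_per_class = 20, shift = 6, seed = 20)
  x <- as.matrix(bf[, c("f1", "f2")])
  y <- bf$label
  for (sigma in c(0.5, 1, 1.5)) {
    m <- fit_classifier(classifier_spec("svm", sigma = sigma), x, y)
    expect_identical(as.character(predict(m, x)), y)
  }
})

test_that("network classifiers train deterministically under a seed", {
  bf <- blob_features(n_per_class = 15, shift = 4, seed = 21)
  x <- scale(as.matrix(bf[, c("f1", "f2")]))
  for (fam in c("ffnn", "cfnn", "rnn")) {
    m1 <- fit_classifier(classifier_spec(fam, seed = 5), x, bf$label)
    m2 <- fit_classifier(classifier_spec(fam, seed = 5), x, bf$label)
    expect_identical(predict(m1, x), predict(m2, x), label = fam)
    expect_gte(mean(as.character(predict(m1, x)) == bf$label), 0.95)
  }
})

test_that("classifier fitting validates its inputs", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_classifier(classifier_spec("knn"), x, rep("focal", 10)),
               "single-class")
  xbad <- x; xbad[1] <- NA
  expect_error(fit_classifier(classifier_spec("knn"), xbad,
                              rep(c("focal", "nonfocal"), 5)), "non-finite")
  m <- fit_classifier(classifier_spec("knn"), x, rep(c("focal", "nonfocal"), 5))
  expect_error(predict(m, matrix(0, 2, 3)), "shape error")
})

test_that("metric arithmetic matches the pooled-count definitions", {
  m <- compute_metrics(50, 50, 0, 0)
  expect_equal(c(m$acc, m$sen, m$spe), c(100, 100, 100))
  m <- compute_metrics(97, 98, 2, 3)
  expect_equal(m$acc, 97.5)
  expect_equal(m$sen, 97.0)
  expect_equal(m$spe, 98.0)
  # list form
  m2 <- compute_metrics(list(tp = 97, tn = 98, fp = 2, fn = 3))
  expect_equal(m, m2)
  expect_error(compute_metrics(0, 5, 0, 0), "SEN")
  expect_error(compute_metrics(5, 0, 0, 0), "SPE")
  # accuracy is a weighted mean of sensitivity and specificity
  set.seed(22)
  for (i in 1:25) {
    cc <- rpois(4, 20) + 1
    m <- compute_metrics(cc[1], cc[2], cc[3], cc[4])
    expect_gte(m$acc, min(m$sen, m$spe) - 1e-9)
    expect_lte(m$acc, max(m$sen, m$spe) + 1e-9)
  }
})

test_that("stratified folds partition every record exactly once", {
  lab <- rep(c("focal", "nonfocal"), each = 25)
  fid <- stratified_folds(lab, 5, seed = 1)
  expect_identical(sort(unique(fid)), 1:5)
  expect_true(all(table(fid) == 10))
  # stratification: each fold balanced
  expect_true(all(table(fid, lab) == 5))
  expect_error(stratified_folds(rep(c("focal", "nonfocal"), c(3, 50)), 5),
               "config error")
})

test_that("cross-validation pools counts over a true partition", {
  bf <- blob_features(n_per_class = 100, shift = 6, seed = 23)
  cv <- cross_validate(bf, classifier_spec("knn", k = 3), folds = 10, seed = 3)
  expect_equal(with(cv$counts, tp + tn + fp + fn), 200)
  expect_equal(sum(cv$fold_detail$n_test), 200)
  expect_gte(cv$metrics$acc, 99)   # 6-sigma shift is essentially separable
  gl <- generics::glance(cv)
  expect_equal(gl$acc, cv$metrics$acc)
  expect_equal(nrow(generics::tidy(cv)), 10)
})

test_that("pure-noise features score near chance", {
  set.seed(24)
  noise <- blob_features(n_per_class = 30, shift = 0, seed = 25)
  cv <- cross_validate(noise, classifier_spec("knn", k = 3), folds = 3, seed = 4)
  expect_gte(cv$metrics$acc, 25)
  expect_lte(cv$metrics$acc, 75)
})

test_that("grid tuning returns the best grid value under one partition", {
  bf <- blob_features(n_per_class = 12, shift = 3, seed = 26)
  tuned <- tune_classifier(bf, "knn", grid = c(1, 3, 5), folds = 3, seed = 5)
  expect_equal(nrow(tuned$results), 3)
  expect_true(all(max(tuned$results$acc) >= tuned$results$acc))
  expect_equal(tuned$best_spec$k, as.integer(tuned$best_value))
  best_acc <- tuned$results$acc[tuned$results$value == tuned$best_value]
  expect_equal(best_acc, max(tuned$results$acc))
})
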