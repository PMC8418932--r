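#' Classification metrics from pooled confusion counts
#'
#' Accuracy, sensitivity and specificity in percent from confusion counts
#' pooled over cross-validation folds:
#' `ACC = (TP + TN) / (TP + TN + FP + FN) * 100`,
#' `SEN = TP / (TP + FN) * 100` (focal detection rate),
#' `SPE = TN / (TN + FP) * 100` (nonfocal detection rate).
#'
#' @param tp,tn,fp,fn Non-negative integer counts.  Alternatively pass a
#'   single list/vector with named elements `tp`, `tn`, `fp`, `fn` as
#'   `tp`.
#' @return A one-row tibble with columns `acc`, `sen`, `spe` (percent).
#' @examples
#' compute_metrics(97, 98, 2, 3)
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp) || (length(tp) == 4L && !is.null(names(tp)))) {
    cc <- tp
    tp <- cc[["tp"]]; tn <- cc[["tn"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("undefined metric ACC: no evaluated records", call. = FALSE)
  if (tp + fn == 0) stop("undefined metric SEN: no positive records", call. = FALSE)
  if (tn + fp == 0) stop("undefined metric SPE: no negative records", call. = FALSE)
  tibble::tibble(
    acc = (tp + tn) / sum(counts) * 100,
    sen = tp / (tp + fn) * 100,
    spe = tn / (tn + fp) * 100
  )
}

#' Stratified fold assignment
#'
#' @param label Class labels.
#' @param folds Number of folds.
#' @param seed RNG seed for the shuffle.
#' @return Integer fold id (1..folds) per record; each class is spread as
#'   evenly as possible across folds.
#' @export
stratified_folds <- function(label, folds, seed = 1) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("config error: 'folds' must be >= 2", call. = FALSE)
  tab <- table(label)
  if (any(tab < folds)) {
    stop("config error: class '", names(tab)[which.min(tab)], "' has ",
         min(tab), " records, fewer than ", folds, " folds", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(label))
  for (cl in names(tab)) {
    idx <- sample(which(label == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

scale_fold <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

#' Stratified k-fold cross-validation with pooled metrics
#'
#' Partitions the records into `folds` stratified subsets; each subset is
#' tested once on a classifier trained on the remaining folds, so every
#' record is tested exactly once.  Features are z-scored with statistics
#' fit on the training split only.  Confusion counts are pooled over the
#' folds before computing accuracy, sensitivity and specificity.
#'
#' @param features A feature table ([feature_table()]): `label` column
#'   plus numeric feature columns (`record` ignored).
#' @param spec A [classifier_spec()].
#' @param folds Number of folds, default 10.
#' @param seed Seed controlling the fold shuffle (and, offset per fold,
#'   network weight initialisation).
#' @param standardize Per-fold z-scoring, default TRUE.
#' @param positive Positive class label, default `"focal"`.
#' @return A `cv_result`: list with `metrics` (tibble: acc/sen/spe),
#'   `counts` (pooled tp/tn/fp/fn), `fold_detail` (per-fold tibble),
#'   `spec`, `folds`, `seed`, `n`, `fold_id`.
#' @export
cross_validate <- function(features, spec, folds = 10, seed = 1,
                           standardize = TRUE, positive = "focal") {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  x <- as_feature_matrix(features)
  y <- as.character(features$label)
  if (!positive %in% y) positive <- y[1L]
  fold_id <- stratified_folds(y, folds, seed)
  tp <- tn <- fp <- fn <- 0L
  detail <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    xtr <- x[!te, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (standardize) {
      sc <- scale_fold(xtr, xte)
      xtr <- sc$train
      xte <- sc$test
    }
    sp <- spec
    sp$seed <- spec$seed + f
    model <- fit_classifier(sp, xtr, y[!te], positive = positive)
    pred <- as.character(stats::predict(model, xte))
    truth <- y[te]
    ftp <- sum(pred == positive & truth == positive)
    ftn <- sum(pred != positive & truth != positive)
    ffp <- sum(pred == positive & truth != positive)
    ffn <- sum(pred != positive & truth == positive)
    tp <- tp + ftp; tn <- tn + ftn; fp <- fp + ffp; fn <- fn + ffn
    detail[[f]] <- tibble::tibble(fold = f, n_test = sum(te),
                                  tp = ftp, tn = ftn, fp = ffp, fn = ffn)
  }
  counts <- list(tp = tp, tn = tn, fp = fp, fn = fn)
  structure(list(metrics = compute_metrics(counts),
                 counts = counts,
                 fold_detail = dplyr::bind_rows(detail),
                 spec = spec, folds = as.integer(folds),
                 seed = as.integer(seed), n = nrow(x),
                 fold_id = fold_id),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<cv_result> %s, %d-fold CV on %d records\n",
              x$spec$family, x$folds, x$n))
  cat(sprintf("  ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  (pooled TP %d TN %d FP %d FN %d)\n",
              m$acc, m$sen, m$spe, x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn))
  invisible(x)
}

#' Hyperparameter grid search under one CV partition
#'
#' Evaluates every grid value with the same stratified partition and
#' returns the grid table plus the best specification (ties broken toward
#' the smaller grid value, mirroring the "best result on the stated grid"
#' reporting convention).  Default grids: `k = 1..9` for KNN,
#' `sigma = seq(0.1, 1.5, 0.1)` for the RBF SVM.
#'
#' @param features Feature table.
#' @param family Classifier family (see [classifier_spec()]).
#' @param grid Numeric vector of grid values; default per family.
#' @param folds,seed,positive Passed to [cross_validate()].
#' @param ... Other [classifier_spec()] arguments held fixed.
#' @return A list with `results` (tibble: value, acc, sen, spe),
#'   `best_spec`, `best_value`.
#' @export
tune_classifier <- function(features, family, grid = NULL, folds = 10,
                            seed = 1, positive = "focal", ...) {
  if (is.null(grid)) {
    grid <- switch(family,
                   knn = 1:9,
                   svm = seq(0.1, 1.5, by = 0.1),
                   stop("no default grid for family '", family, "'", call. = FALSE))
  }
  rows <- lapply(grid, function(v) {
    spec <- if (family == "knn") classifier_spec("knn", k = v, ...)
            else classifier_spec(family, sigma = v, ...)
    cv <- cross_validate(features, spec, folds = folds, seed = seed,
                         positive = positive)
    dplyr::bind_cols(tibble::tibble(value = v), cv$metrics)
  })
  results <- dplyr::bind_rows(rows)
  best <- which.max(results$acc)
  best_spec <- if (family == "knn") classifier_spec("knn", k = results$value[best], ...)
               else classifier_spec(family, sigma = results$value[best], ...)
  list(results = results, best_spec = best_spec, best_value = results$value[best])
}
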