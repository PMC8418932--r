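#' Classifier specification
#'
#' Describes one of the six classifier families with its hyperparameters:
#'
#' * `"knn"` — k-nearest neighbour with city-block (L1) distance;
#'   `k` in 1..9 (default 3).
#' * `"svm"` — support vector machine with RBF kernel
#'   `exp(-||u - v||^2 / (2 * sigma^2))`; `sigma` on the grid 0.1..1.5
#'   (default 1).
#' * `"ffnn"` — single-hidden-layer feed-forward network, `hidden = 10`
#'   tan-sigmoid-equivalent units, second-order (BFGS) training.
#' * `"cfnn"` — cascade-forward network: the feed-forward net plus direct
#'   input-to-output (skip-layer) connections.
#' * `"grnn"` — generalised regression network (Gaussian kernel
#'   regression on class indicators); `spread` defaults to 1.
#' * `"rnn"` — Elman-style recurrent network: hidden layer plus a context
#'   layer copied from the hidden state.  Each record is a length-1
#'   sequence, so the context units enter at their zero initial state.
#'
#' @param family One of `"knn"`, `"svm"`, `"ffnn"`, `"cfnn"`, `"grnn"`,
#'   `"rnn"`.
#' @param k Neighbour count for `"knn"`.
#' @param sigma RBF width for `"svm"`.
#' @param hidden Hidden-unit count for the networks (default 10).
#' @param spread Kernel width for `"grnn"`.
#' @param maxit Maximum training epochs for the networks (default 200).
#' @param decay Weight decay for the networks (default 5e-4).
#' @param seed RNG seed used for network weight initialisation.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(family = c("knn", "svm", "ffnn", "cfnn", "grnn", "rnn"),
                            k = 3, sigma = 1, hidden = 10, spread = 1,
                            maxit = 200, decay = 5e-4, seed = 1) {
  family <- match.arg(family)
  structure(list(family = family, k = as.integer(k), sigma = sigma,
                 hidden = as.integer(hidden), spread = spread,
                 maxit = as.integer(maxit), decay = decay,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- switch(x$family,
               knn = sprintf("k = %d, city-block", x$k),
               svm = sprintf("RBF sigma = %g", x$sigma),
               grnn = sprintf("spread = %g", x$spread),
               sprintf("hidden = %d", x$hidden))
  cat(sprintf("<classifier_spec> %s (%s)\n", x$family, hp))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- x[, !(names(x) %in% c("record", "label")), drop = FALSE]
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("numeric error: non-finite feature values", call. = FALSE)
  m
}

check_labels <- function(y, positive) {
  y <- as.character(y)
  lv <- unique(y)
  if (length(lv) < 2L) stop("value error: single-class training set", call. = FALSE)
  if (length(lv) > 2L) stop("value error: expected a binary label", call. = FALSE)
  if (!positive %in% lv) stop("positive class '", positive, "' absent", call. = FALSE)
  factor(y, levels = c(positive, setdiff(lv, positive)))
}

cityblock_cross <- function(a, b) {
  # |a_i - b_j|_1 cross-distance matrix, rows of a x rows of b
  out <- matrix(0, nrow(a), nrow(b))
  for (d in seq_len(ncol(a))) {
    out <- out + abs(outer(a[, d], b[, d], "-"))
  }
  out
}

#' Fit a classifier
#'
#' Trains one classifier on a feature matrix.  Feature scaling is the
#' caller's responsibility ([cross_validate()] standardises per training
#' fold); instance-based families (`knn`, `grnn`) simply store the
#' training data.
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix or data frame (bookkeeping columns
#'   `record`/`label` are dropped if present).
#' @param y Binary labels, one per row.
#' @param positive The positive (focal) class, default `"focal"`; when
#'   absent from `y`, the first label value encountered is used.
#' @return A fitted model of class `eeg_model`, usable with [predict()].
#' @export
fit_classifier <- function(spec, x, y, positive = "focal") {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as_feature_matrix(x)
  if (!positive %in% y) positive <- as.character(y)[1L]
  y <- check_labels(y, positive)
  if (min(table(y)) < 1L) stop("value error: empty class", call. = FALSE)
  if (nrow(x) != length(y)) stop("rows of 'x' must match 'y'", call. = FALSE)

  fit <- switch(
    spec$family,
    knn = list(train_x = x, train_y = y),
    grnn = list(train_x = x, train_y = y),
    svm = {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(spec$seed)
      e1071::svm(x, y, type = "C-classification", kernel = "radial",
                 gamma = 1 / (2 * spec$sigma^2), scale = FALSE)
    },
    ffnn = fit_net(x, y, spec, skip = FALSE, context = 0L),
    cfnn = fit_net(x, y, spec, skip = TRUE, context = 0L),
    rnn = fit_net(x, y, spec, skip = FALSE, context = spec$hidden)
  )
  structure(list(spec = spec, fit = fit, positive = levels(y)[1L],
                 negative = levels(y)[2L], p = ncol(x)),
            class = "eeg_model")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

fit_net <- function(x, y, spec, skip, context) {
  if (context > 0L) {
    # Elman context units: zero initial state for length-1 sequences; the
    # weights from these inputs are the recurrent (context -> hidden) block.
    x <- cbind(x, matrix(0, nrow(x), context,
                         dimnames = list(NULL, sprintf("ctx%02d", seq_len(context)))))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  net <- nnet::nnet(x, as.numeric(y == levels(y)[1L]), size = spec$hidden,
                    decay = spec$decay, maxit = spec$maxit, skip = skip,
                    entropy = TRUE, trace = FALSE)
  list(net = net, context = context)
}

#' @export
predict.eeg_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$p) {
    stop("shape error: model trained on ", object$p, " features, got ",
         ncol(x), call. = FALSE)
  }
  spec <- object$spec
  pos <- object$positive
  neg <- object$negative
  out <- switch(
    spec$family,
    knn = {
      d <- cityblock_cross(x, object$fit$train_x)
      apply_knn_vote(d, object$fit$train_y, spec$k, pos, neg)
    },
    grnn = {
      # squared Euclidean cross-distances
      d2 <- outer(rowSums(x^2), rep(1, nrow(object$fit$train_x))) +
        outer(rep(1, nrow(x)), rowSums(object$fit$train_x^2)) -
        2 * x %*% t(object$fit$train_x)
      w <- exp(-pmax(d2, 0) / (2 * spec$spread^2))
      score <- as.vector(w %*% (object$fit$train_y == pos)) / pmax(rowSums(w), 1e-300)
      ifelse(score >= 0.5, pos, neg)
    },
    svm = as.character(stats::predict(object$fit, x)),
    {
      ctx <- object$fit$context
      if (ctx > 0L) x <- cbind(x, matrix(0, nrow(x), ctx))
      p <- as.vector(stats::predict(object$fit$net, x))
      ifelse(p >= 0.5, pos, neg)
    }
  )
  factor(out, levels = c(pos, neg))
}

apply_knn_vote <- function(d, train_y, k, pos, neg) {
  k <- min(k, ncol(d))
  vapply(seq_len(nrow(d)), function(i) {
    ord <- order(d[i, ], decreasing = FALSE)[seq_len(k)]
    votes <- train_y[ord]
    n_pos <- sum(votes == pos)
    if (n_pos * 2L == k) {
      # tie: side with the nearer summed distance, then the positive class
      dp <- sum(d[i, ord][votes == pos])
      dn <- sum(d[i, ord][votes != pos])
      if (dp <= dn) pos else neg
    } else if (n_pos * 2L > k) pos else neg
  }, character(1))
}
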