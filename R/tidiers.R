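#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return One row per feature: `feature` (name or index), `selected`.
#' @export
tidy.selection_result <- function(x, ...) {
  nm <- x$feature_names
  if (is.null(nm)) nm <- sprintf("f%03d", seq_along(x$mask))
  tibble::tibble(feature = nm, selected = x$mask != 0)
}

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_selected = x$n_selected,
                 dimension = length(x$mask), best_fitness = x$best_fitness,
                 n_evals = x$n_evals, seed = x$seed)
}

#' Convergence plot of a selector run
#'
#' Best-so-far fitness per iteration (index 0 is the evaluated initial
#' population).
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$history) - 1L,
                       best_fitness = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best-so-far fitness",
                  title = sprintf("%s: %d/%d features, fitness %.3g",
                                  toupper(object$method), object$n_selected,
                                  length(object$mask), object$best_fitness)) +
    ggplot2::theme_minimal()
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Per-fold confusion counts as a tibble.
#' @export
tidy.cv_result <- function(x, ...) x$fold_detail

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(classifier = x$spec$family, folds = x$folds, n = x$n),
    x$metrics,
    tibble::as_tibble(x$counts)
  )
}

#' Pooled-metric bar plot for a pipeline report
#'
#' @param object A `pipeline_report`.
#' @param ... Unused.
#' @return A ggplot of accuracy, sensitivity and specificity per
#'   classifier.
#' @export
autoplot.pipeline_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$leaderboard,
                              cols = c("acc", "sen", "spe"),
                              names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier, y = .data$percent,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("Pooled %d-fold CV (selector: %s, %d features)",
                                  object$config$folds, object$config$selector,
                                  length(object$features_used))) +
    ggplot2::theme_minimal()
}

#' Subband frequency-layout plot
#'
#' Centre frequency and bandwidth of every subband of a TQWT design.
#'
#' @param object A [tqwt_params()] object.
#' @param fs Sampling rate in Hz (default 512).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tqwt_params <- function(object, fs = 512, ...) {
  df <- subband_frequencies(object, fs = fs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subband, y = .data$fc_hz)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$fc_hz - .data$bw_hz / 2, 0),
                                          ymax = .data$fc_hz + .data$bw_hz / 2,
                                          colour = .data$type)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "subband", y = "frequency (Hz)",
                  title = sprintf("TQWT bands: Q = %g, r = %g, J = %d",
                                  object$Q, object$r, object$J)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
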