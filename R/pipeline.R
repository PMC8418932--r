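#' End-to-end focal/nonfocal discrimination run
#'
#' Orchestrates the full path: channel difference and first differencing,
#' TQWT decomposition, four entropies per subband, optional feature
#' screening or metaheuristic selection, and stratified k-fold evaluation
#' of one or more classifiers with pooled accuracy, sensitivity and
#' specificity.
#'
#' @param records A named list of [eeg_record()]s (e.g. [synth_dataset()]
#'   or [read_eeg_dataset()]).
#' @param Q,r TQWT controls (defaults 3 and 3, the operating point).
#' @param J Decomposition depth; `NULL` (default) uses
#'   `min(26, max levels)` for the record length at hand.
#' @param eps,log_base Entropy configuration.
#' @param selector `"none"` (all features), `"kws"` (keep features with
#'   Kruskal-Wallis p < 0.05), or one of `"bba"`, `"bde"`, `"fa"`,
#'   `"ga"`, `"gwo"`, `"pso"`.
#' @param classifier Character vector of families (`"all"` for all six),
#'   or a list of [classifier_spec()]s.  The first entry also serves as
#'   the wrapper-fitness classifier for metaheuristic selectors.
#' @param folds Evaluation CV folds (default 10).
#' @param fitness_folds Wrapper-fitness CV folds for the selectors
#'   (default `folds`; smaller values cut wrapper cost substantially).
#' @param seed Master seed: fold partitions, selector RNG and network
#'   initialisation all derive from it.
#' @param selector_args Named list of extra arguments for the selector
#'   (e.g. `list(iterations = 30)`).
#' @return A `pipeline_report`: list with `config`, `selection`,
#'   `features_used`, `leaderboard` (tibble: classifier, acc, sen, spe,
#'   n_features), and `cv` (named list of `cv_result`s).
#' @examples
#' \donttest{
#' recs <- synth_dataset(synth_config(n_per_class = 12, duration = 0.5))
#' rep <- run_pipeline(recs, J = 5, selector = "none", classifier = "knn",
#'                     folds = 3)
#' rep$leaderboard
#' }
#' @export
run_pipeline <- function(records, Q = 3, r = 3, J = NULL, eps = 0.2,
                         log_base = exp(1),
                         selector = c("none", "kws", "bba", "bde", "fa", "ga", "gwo", "pso"),
                         classifier = "knn", folds = 10, fitness_folds = folds,
                         seed = 1, selector_args = list()) {
  selector <- match.arg(selector)
  n_sig <- length(records[[1L]]$x) - 1L          # differenced length
  if (is.null(J)) J <- min(26L, tqwt_max_levels(n_sig, Q, r))
  specs <- resolve_classifiers(classifier, seed)

  features <- feature_table(records, Q = Q, r = r, J = J,
                            eps = eps, log_base = log_base)
  selection <- NULL
  used <- features
  if (selector == "kws") {
    selection <- kws_screen(features)
    used <- apply_mask(features, selection)
  } else if (selector != "none") {
    selection <- do.call(select_features,
                         c(list(features = features, method = selector,
                                spec = specs[[1L]], folds = fitness_folds,
                                seed = seed),
                           selector_args))
    used <- apply_mask(features, selection)
  }

  cvs <- lapply(specs, function(sp) {
    cross_validate(used, sp, folds = folds, seed = seed)
  })
  names(cvs) <- vapply(specs, function(sp) sp$family, character(1))
  leaderboard <- dplyr::bind_rows(lapply(names(cvs), function(nm) {
    dplyr::bind_cols(tibble::tibble(classifier = nm), cvs[[nm]]$metrics,
                     tibble::tibble(n_features = length(feature_columns(used))))
  }))
  leaderboard <- dplyr::arrange(leaderboard, dplyr::desc(.data$acc))

  structure(list(
    config = list(Q = Q, r = r, J = J, eps = eps, log_base = log_base,
                  selector = selector, folds = folds,
                  fitness_folds = fitness_folds, seed = seed,
                  n_records = length(records),
                  classifiers = names(cvs),
                  version = as.character(pkg_version())),
    selection = selection,
    features_used = feature_columns(used),
    leaderboard = leaderboard,
    cv = cvs
  ), class = "pipeline_report")
}

pkg_version <- function() {
  tryCatch(utils::packageVersion("eegfocus"), error = function(e) "dev")
}

resolve_classifiers <- function(classifier, seed) {
  all_families <- c("knn", "svm", "ffnn", "cfnn", "grnn", "rnn")
  if (is.list(classifier)) {
    stopifnot(all(vapply(classifier, inherits, logical(1), "classifier_spec")))
    return(classifier)
  }
  fams <- if (identical(classifier, "all")) all_families else classifier
  if (!all(fams %in% all_families)) {
    stop("unknown classifier(s): ",
         paste(setdiff(fams, all_families), collapse = ", "), call. = FALSE)
  }
  lapply(fams, function(f) classifier_spec(f, seed = seed))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> Q = %g, r = %g, J = %d, selector = %s, %d features used\n",
              x$config$Q, x$config$r, x$config$J, x$config$selector,
              length(x$features_used)))
  print(x$leaderboard)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (config echo, selection, pooled counts and
#' metrics) and `leaderboard.csv` so a run can be reconstructed.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sel <- report$selection
  if (inherits(sel, "selection_result")) {
    sel <- list(method = sel$method, mask = sel$mask,
                best_fitness = sel$best_fitness, history = sel$history,
                n_selected = sel$n_selected, seed = sel$seed,
                config = sel$config, selected = sel$selected)
  }
  out <- list(config = report$config, selection = sel,
              features_used = report$features_used,
              results = lapply(report$cv, function(cv) {
                list(counts = cv$counts, metrics = as.list(cv$metrics),
                     folds = cv$folds, seed = cv$seed)
              }))
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$leaderboard, file.path(dir, "leaderboard.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' TQWT parameter selection, step 1: classifier ranking
#'
#' Extracts entropy features at the fixed starting point Q = 2, r = 2,
#' J = 5 and ranks the configured classifiers by pooled CV accuracy.
#'
#' @param records Named list of [eeg_record()]s.
#' @param classifier Families or specs, as in [run_pipeline()]
#'   (default `"all"`).
#' @param folds,seed,eps,log_base As in [run_pipeline()].
#' @return A tibble (classifier, acc, sen, spe) sorted by decreasing
#'   accuracy.
#' @export
sweep_step1 <- function(records, classifier = "all", folds = 10, seed = 1,
                        eps = 0.2, log_base = exp(1)) {
  specs <- resolve_classifiers(classifier, seed)
  if (length(specs) < 2L) {
    stop("step 1 ranks classifiers; configure at least 2", call. = FALSE)
  }
  features <- feature_table(records, Q = 2, r = 2, J = 5,
                            eps = eps, log_base = log_base)
  rows <- lapply(specs, function(sp) {
    cv <- cross_validate(features, sp, folds = folds, seed = seed)
    dplyr::bind_cols(tibble::tibble(classifier = sp$family), cv$metrics)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$acc))
}

#' TQWT parameter selection, step 2: (Q, r) grid
#'
#' Scans Q over 2..10 and r over 2..5 at fixed J = 5 with the chosen
#' classifier; ties break toward smaller Q, then smaller r.
#'
#' @param records Named list of [eeg_record()]s.
#' @param spec The classifier chosen in step 1 ([classifier_spec()]).
#' @param Q_grid,r_grid Grids (defaults 2:10 and 2:5).
#' @param J Fixed depth during the scan (default 5).
#' @param folds,seed,eps,log_base As in [run_pipeline()].
#' @return A list with `grid` (tibble: Q, r, acc, sen, spe), `best_Q`,
#'   `best_r`.
#' @export
sweep_step2 <- function(records, spec, Q_grid = 2:10, r_grid = 2:5, J = 5,
                        folds = 10, seed = 1, eps = 0.2, log_base = exp(1)) {
  stopifnot(inherits(spec, "classifier_spec"))
  rows <- list()
  for (Q in Q_grid) for (r in r_grid) {
    features <- feature_table(records, Q = Q, r = r, J = J,
                              eps = eps, log_base = log_base)
    cv <- cross_validate(features, spec, folds = folds, seed = seed)
    rows[[length(rows) + 1L]] <-
      dplyr::bind_cols(tibble::tibble(Q = Q, r = r), cv$metrics)
  }
  grid <- dplyr::bind_rows(rows)
  ord <- order(-grid$acc, grid$Q, grid$r)
  list(grid = grid, best_Q = grid$Q[ord[1L]], best_r = grid$r[ord[1L]])
}

#' TQWT parameter selection, step 3: depth scan
#'
#' Scans the decomposition depth J at the chosen (Q, r); depths exceeding
#' the admissible maximum for the record length are skipped with a
#' warning.  Ties break toward the smaller J.
#'
#' @param records Named list of [eeg_record()]s.
#' @param spec Chosen classifier ([classifier_spec()]).
#' @param Q,r Chosen TQWT controls.
#' @param J_range Depths to scan (default 5:35).
#' @param folds,seed,eps,log_base As in [run_pipeline()].
#' @return A list with `scan` (tibble: J, acc, sen, spe) and `best_J`.
#' @export
sweep_step3 <- function(records, spec, Q = 3, r = 3, J_range = 5:35,
                        folds = 10, seed = 1, eps = 0.2, log_base = exp(1)) {
  stopifnot(inherits(spec, "classifier_spec"))
  n_sig <- length(records[[1L]]$x) - 1L
  jmax <- tqwt_max_levels(n_sig, Q, r)
  if (any(J_range > jmax)) {
    warning("skipping J > ", jmax, " (maximum level for length ", n_sig, ")",
            call. = FALSE)
    J_range <- J_range[J_range <= jmax]
  }
  if (length(J_range) == 0L) stop("empty J range after capping", call. = FALSE)
  rows <- lapply(J_range, function(J) {
    features <- feature_table(records, Q = Q, r = r, J = J,
                              eps = eps, log_base = log_base)
    cv <- cross_validate(features, spec, folds = folds, seed = seed)
    dplyr::bind_cols(tibble::tibble(J = J), cv$metrics)
  })
  scan <- dplyr::bind_rows(rows)
  ord <- order(-scan$acc, scan$J)
  list(scan = scan, best_J = scan$J[ord[1L]])
}
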