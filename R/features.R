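#' Entropy features for one record
#'
#' The per-record feature path: channel difference X - Y, first
#' differencing, TQWT decomposition, four entropies per subband.
#'
#' @param record An [eeg_record()].
#' @param params A [tqwt_params()]; alternatively `Q`, `r`, `J`.
#' @param Q,r,J Used when `params` is missing.
#' @param eps,log_base Entropy configuration, see [subband_entropies()].
#' @return Named numeric vector of length `4 * (J + 1)`.
#' @export
record_features <- function(record, params = NULL, Q = 3, r = 3, J = 3,
                            eps = 0.2, log_base = exp(1)) {
  stopifnot(inherits(record, "eeg_record"))
  if (is.null(params)) params <- tqwt_params(Q, r, J)
  s <- differencing(channel_difference(record))
  subband_entropies(tqwt_decompose(s, params), eps = eps, log_base = log_base)
}

#' Entropy feature table for a set of records
#'
#' Applies [record_features()] to every record and assembles a tidy
#' feature table: one row per record, one column per entropy feature,
#' plus `record` (identifier) and `label` columns.
#'
#' @param records A list of [eeg_record()] objects (e.g. from
#'   [synth_dataset()]), or a character vector of file paths read with
#'   [read_eeg_record()].
#' @param params,Q,r,J,eps,log_base See [record_features()].
#' @param labels Optional character vector overriding the records' own
#'   labels (recycled checks apply).
#' @return A tibble with columns `record`, `label`, then the
#'   `4 * (J + 1)` feature columns.
#' @export
feature_table <- function(records, params = NULL, Q = 3, r = 3, J = 3,
                          eps = 0.2, log_base = exp(1), labels = NULL) {
  if (is.character(records)) {
    paths <- records
    records <- lapply(paths, read_eeg_record)
    ids <- basename(paths)
  } else {
    ids <- names(records)
    if (is.null(ids)) ids <- sprintf("record_%03d", seq_along(records))
  }
  if (is.null(params)) params <- tqwt_params(Q, r, J)
  if (is.null(labels)) {
    labels <- vapply(records, function(r) r$label, character(1))
  }
  if (length(labels) != length(records)) {
    stop("'labels' must match the number of records", call. = FALSE)
  }
  rows <- lapply(records, record_features, params = params,
                 eps = eps, log_base = log_base)
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(
    tibble::tibble(record = ids, label = labels),
    tibble::as_tibble(mat)
  )
}

feature_columns <- function(features) {
  setdiff(names(features), c("record", "label"))
}

check_two_classes <- function(label) {
  tab <- table(label)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("value error: need both classes with at least 2 records each; got ",
         paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
         call. = FALSE)
  }
  invisible(tab)
}

#' Kruskal-Wallis feature screening
#'
#' Rank-based two-sample screen of every feature column against the class
#' label; features with p below `alpha` (default 0.05) are flagged as
#' discriminative.  With two groups this is the Kruskal-Wallis test used
#' throughout the focal-detection literature (equivalent to a Wilcoxon
#' rank-sum test up to the chi-squared approximation).
#'
#' @param features A feature table from [feature_table()] (columns
#'   `record`, `label`, features), or any data frame with a `label`
#'   column and numeric feature columns.
#' @param alpha Significance level for the `keep` flag, default 0.05.
#' @return A tibble with columns `feature`, `statistic`, `p_value`,
#'   `keep`, ordered as the feature columns.
#' @export
kws_screen <- function(features, alpha = 0.05) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  check_two_classes(features$label)
  cols <- feature_columns(features)
  g <- factor(features$label)
  res <- lapply(cols, function(cn) {
    kt <- stats::kruskal.test(features[[cn]], g)
    tibble::tibble(feature = cn,
                   statistic = unname(kt$statistic),
                   p_value = kt$p.value)
  })
  dplyr::mutate(dplyr::bind_rows(res), keep = .data$p_value < alpha)
}

#' Apply a feature mask or screening result
#'
#' Restricts a feature table to the selected feature columns, keeping the
#' `record`/`label` bookkeeping columns.
#'
#' @param features A feature table.
#' @param mask Either a 0/1 (or logical) vector over the feature columns,
#'   a character vector of feature names, a [kws_screen()] result (its
#'   `keep` column is used), or a selection result from
#'   [select_features()].
#' @return The masked feature table.
#' @export
apply_mask <- function(features, mask) {
  cols <- feature_columns(features)
  if (inherits(mask, "selection_result")) mask <- mask$mask
  if (is.data.frame(mask) && all(c("feature", "keep") %in% names(mask))) {
    keep <- mask$feature[mask$keep]
  } else if (is.character(mask)) {
    keep <- mask
  } else {
    mask <- as.logical(mask)
    if (length(mask) != length(cols)) {
      stop("mask length ", length(mask), " does not match ", length(cols),
           " feature columns", call. = FALSE)
    }
    keep <- cols[mask]
  }
  if (length(keep) == 0L) stop("mask selects no features", call. = FALSE)
  if (!all(keep %in% cols)) {
    stop("unknown feature(s): ", paste(setdiff(keep, cols), collapse = ", "),
         call. = FALSE)
  }
  features[, c("record", "label", keep)[c("record", "label", keep) %in% names(features)]]
}
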