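# Small shared fixtures, generated once per test run.
small_cfg <- synth_config(n_per_class = 10, duration = 0.5, seed = 101)
small_records <- synth_dataset(small_cfg)
small_features <- feature_table(small_records, Q = 3, r = 3, J = 5)

# two well-separated Gaussian blobs as a plain feature table
blob_features <- function(n_per_class = 20, p = 2, shift = 6, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = shift), ncol = p))
  colnames(x) <- sprintf("f%d", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(record = sprintf("r%03d", seq_len(2 * n_per_class)),
                   label = rep(c("focal", "nonfocal"), each = n_per_class)),
    tibble::as_tibble(x)
  )
}

rel_l2_error <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
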