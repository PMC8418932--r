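#' Synthetic EEG generator configuration
#'
#' Seeded generator of focal-like and nonfocal-like two-channel records
#' emulating the shape of the Bern-Barcelona data (two adjacent channels,
#' 512 Hz, 20 s) and the qualitative contrast the method exploits: the
#' focal-like class is more rhythmic (a few 4-12 Hz sinusoids plus a
#' narrowband AR(2) process and low-variance white noise), the
#' nonfocal-like class more random (broadband AR(2) with a wider pole
#' spread plus higher-variance white noise).  Both channels share a common
#' interference term (mains sinusoid plus slow drift) that the X - Y
#' channel difference cancels.
#'
#' @param n_per_class Records per class (default 50).
#' @param fs Sampling rate in Hz (default 512).
#' @param duration Record length in seconds (default 20; short runs use
#'   2).
#' @param focal_rhythm_freqs Two-element range (Hz) the focal sinusoid
#'   and narrowband-pole frequencies are drawn from (default 4-12 Hz).
#' @param focal_noise_sd,nonfocal_noise_sd White-noise standard
#'   deviations; the nonfocal level must exceed the focal one (defaults
#'   0.3 and 1).
#' @param focal_ar,nonfocal_ar Optional fixed AR coefficient vectors per
#'   class (the simulated process is rescaled to a fixed amplitude for
#'   the focal class).  `NULL` (default) uses an amplitude-modulated
#'   rhythm-band carrier for the focal texture and a per-record 1/f-like
#'   AR(2) (pole radius 0.85 at a 2-20 Hz angle) for the nonfocal
#'   background.
#' @param seed Base seed; every record's stream is derived from it.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_per_class = 50, fs = 512, duration = 20,
                         focal_rhythm_freqs = c(4, 12),
                         focal_noise_sd = 0.3, nonfocal_noise_sd = 1,
                         focal_ar = NULL, nonfocal_ar = NULL, seed = 1) {
  if (n_per_class < 1) stop("'n_per_class' must be >= 1", call. = FALSE)
  if (fs * duration < 64) stop("'fs * duration' must be >= 64 samples", call. = FALSE)
  if (nonfocal_noise_sd <= focal_noise_sd) {
    stop("'nonfocal_noise_sd' must exceed 'focal_noise_sd' (the nonfocal ",
         "class is the more random one)", call. = FALSE)
  }
  if (length(focal_rhythm_freqs) != 2L || diff(focal_rhythm_freqs) <= 0) {
    stop("'focal_rhythm_freqs' must be an increasing (low, high) pair", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class), fs = fs,
                 duration = duration, focal_rhythm_freqs = focal_rhythm_freqs,
                 focal_noise_sd = focal_noise_sd,
                 nonfocal_noise_sd = nonfocal_noise_sd,
                 focal_ar = focal_ar, nonfocal_ar = nonfocal_ar,
                 seed = as.integer(seed)),
            class = "synth_config")
}

record_seed <- function(cfg, class, index) {
  (cfg$seed * 10007L + index * 2L + (class == "focal")) %% 2147483629L
}

#' Generate one synthetic record
#'
#' Deterministic given `(class, cfg$seed, index)`.
#'
#' @param class `"focal"` or `"nonfocal"`.
#' @param cfg A [synth_config()].
#' @param index Record index within its class (1-based).
#' @return An [eeg_record()] of `round(fs * duration)` samples.
#' @export
synth_record <- function(class, cfg, index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!class %in% c("focal", "nonfocal")) {
    stop("value error: class must be 'focal' or 'nonfocal', got '", class, "'",
         call. = FALSE)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(record_seed(cfg, class, index))
  n <- round(cfg$fs * cfg$duration)
  t <- (seq_len(n) - 1) / cfg$fs
  lo <- cfg$focal_rhythm_freqs[1L]
  hi <- cfg$focal_rhythm_freqs[2L]

  if (class == "focal") {
    n_sin <- sample(2:3, 1L)
    freqs <- stats::runif(n_sin, lo, hi)
    amps <- stats::runif(n_sin, 0.8, 1.4)
    phases <- stats::runif(n_sin, 0, 2 * pi)
    rhythm <- rowSums(vapply(seq_len(n_sin),
                             function(k) amps[k] * sin(2 * pi * freqs[k] * t + phases[k]),
                             numeric(n)))
    if (is.null(cfg$focal_ar)) {
      # narrowband texture as a slowly AM-modulated rhythm-band carrier;
      # an AR(2) pole at these angles (a few Hz at fs = 512) would
      # resonate at DC instead of its own frequency
      f0 <- stats::runif(1, lo, hi)
      env <- as.numeric(stats::arima.sim(list(ar = 0.995), n, sd = 1,
                                         n.start = round(cfg$fs)))
      env <- env / stats::sd(env) * 0.4
      texture <- env * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
    } else {
      texture <- as.numeric(stats::arima.sim(list(ar = cfg$focal_ar), n, sd = 1,
                                             n.start = round(cfg$fs)))
      texture <- texture / stats::sd(texture) * 0.4
    }
    s <- rhythm + texture + stats::rnorm(n, 0, cfg$focal_noise_sd)
  } else {
    ar <- cfg$nonfocal_ar
    if (is.null(ar)) {
      # low-frequency-weighted coloured noise (1/f-like background EEG):
      # a moderately damped pole at a 2-20 Hz angle
      rho <- 0.85
      theta <- 2 * pi * stats::runif(1, 2, 20) / cfg$fs
      ar <- c(2 * rho * cos(theta), -rho^2)
    }
    s <- as.numeric(stats::arima.sim(list(ar = ar), n, sd = 1,
                                     n.start = round(cfg$fs))) +
      stats::rnorm(n, 0, cfg$nonfocal_noise_sd)
  }

  # interference common to both channels: mains hum + slow drift
  interference <- 3 * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi)) +
    2 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
  x <- s + interference + stats::rnorm(n, 0, 0.05)
  y <- 0.4 * s + interference + stats::rnorm(n, 0, 0.05)
  eeg_record(x, y, fs = cfg$fs, label = class)
}

#' Generate a balanced labeled dataset
#'
#' @param cfg A [synth_config()].
#' @return A named list of `2 * n_per_class` [eeg_record()]s (all focal
#'   records first) with a `manifest` attribute: a tibble with columns
#'   `record`, `label`, `seed`.
#' @export
synth_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  classes <- c("focal", "nonfocal")
  records <- list()
  manifest <- list()
  for (cl in classes) {
    for (i in seq_len(cfg$n_per_class)) {
      id <- sprintf("%s_%03d", cl, i)
      records[[id]] <- synth_record(cl, cfg, i)
      manifest[[id]] <- tibble::tibble(record = id, label = cl,
                                       seed = record_seed(cfg, cl, i))
    }
  }
  attr(records, "manifest") <- dplyr::bind_rows(manifest)
  records
}

#' Write a dataset to two-column ASCII files
#'
#' Emits one file per record in the dialect [read_eeg_record()] parses,
#' plus a `manifest.csv` (filename, label, seed) carrying the labels,
#' which the record files themselves do not encode.
#'
#' @param records A list from [synth_dataset()] (or any named list of
#'   [eeg_record()]s).
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with a `file` column), invisibly.
#' @export
write_eeg_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(records)
  if (is.null(ids)) ids <- sprintf("record_%03d", seq_along(records))
  files <- file.path(dir, paste0(ids, ".txt"))
  for (i in seq_along(records)) write_eeg_record(records[[i]], files[i])
  manifest <- tibble::tibble(
    file = basename(files),
    record = ids,
    label = vapply(records, function(r) r$label, character(1)),
    fs = vapply(records, function(r) r$fs, numeric(1))
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset directory written by [write_eeg_dataset()]
#'
#' @param dir Directory containing record files and `manifest.csv`.
#' @return A named list of [eeg_record()]s with labels from the manifest.
#' @export
read_eeg_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    read_eeg_record(file.path(dir, manifest$file[i]),
                    fs = manifest$fs[i], label = manifest$label[i])
  })
  names(records) <- manifest$record
  attr(records, "manifest") <- tibble::as_tibble(manifest)
  records
}
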