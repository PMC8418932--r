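#' Subband entropies
#'
#' Four entropy measures computed on one subband's coefficient sequence
#' `s`:
#'
#' * `entropy_le()` — log-energy entropy `sum(log(s_i^2))`, with the
#'   convention that a zero coefficient contributes 0 (as the reference
#'   `wentropy`-style routines do).
#' * `entropy_ll2()` — log of the summed squared coefficients
#'   `log(sum(s_i^2))`; an all-zero subband returns 0 with a warning to
#'   keep feature vectors finite.
#' * `entropy_sure()` — Stein's unbiased risk estimate style entropy
#'   `n - #\{|s_i| <= eps\} + sum(min(s_i^2, eps^2))`.
#' * `entropy_th()` — threshold entropy, the count of coefficients with
#'   `|s_i| > eps`.
#'
#' Thresholding compares `|s_i|` (wavelet coefficients are signed); ties
#' at exactly `eps` count as below threshold.  The natural log is the
#' default, matching the reference implementation route; set
#' `log_base = 2` for base-2.
#'
#' @param s Numeric coefficient vector (non-empty).
#' @param eps Positive threshold, default 0.2.
#' @param log_base Base of the logarithm for `entropy_le()` and
#'   `entropy_ll2()`; default `exp(1)`.
#' @return A single numeric value.
#' @examples
#' entropy_le(c(2, 0.5))                  # log(4) + log(0.25) = 0
#' entropy_sure(c(0.1, 0.3, 0.5), 0.2)    # 2.09
#' entropy_th(c(0.1, 0.3, 0.5), 0.2)      # 2
#' @name subband_entropy
NULL

check_subband <- function(s) {
  if (length(s) == 0L) stop("value error: empty coefficient sequence", call. = FALSE)
  if (!is.numeric(s)) stop("value error: coefficients must be numeric", call. = FALSE)
  invisible(s)
}

#' @rdname subband_entropy
#' @export
entropy_le <- function(s, log_base = exp(1)) {
  check_subband(s)
  s2 <- s^2
  nz <- s2 > 0
  sum(log(s2[nz], base = log_base))
}

#' @rdname subband_entropy
#' @export
entropy_ll2 <- function(s, log_base = exp(1)) {
  check_subband(s)
  e <- sum(s^2)
  if (e == 0) {
    warning("all-zero subband: LL2 entropy set to 0", call. = FALSE)
    return(0)
  }
  log(e, base = log_base)
}

#' @rdname subband_entropy
#' @export
entropy_sure <- function(s, eps = 0.2) {
  check_subband(s)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    stop("value error: 'eps' must be a single positive number", call. = FALSE)
  }
  n <- length(s)
  n - sum(abs(s) <= eps) + sum(pmin(s^2, eps^2))
}

#' @rdname subband_entropy
#' @export
entropy_th <- function(s, eps = 0.2) {
  check_subband(s)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    stop("value error: 'eps' must be a single positive number", call. = FALSE)
  }
  sum(abs(s) > eps)
}

#' Entropy feature vector of a subband set
#'
#' Computes the four entropies for each of the `J + 1` subbands and
#' concatenates them in entropy-major order: all log-energy values
#' (subband 1 .. J+1), then all LL2, SURE, and threshold values, for a
#' total of `4 * (J + 1)` features.  At the operating point J = 26 this is
#' the 108-element vector fed to the classifiers.  Feature names follow
#' `"{LE|LL2|SURE|TH}_{D01..DJ|A}"` with `A` the approximation.
#'
#' @param subbands A `tqwt_subbands` object from [tqwt_decompose()].
#' @param eps SURE/threshold entropy threshold, default 0.2.
#' @param log_base Log base for LE and LL2, default natural.
#' @return A named numeric vector of length `4 * (J + 1)`.
#' @export
subband_entropies <- function(subbands, eps = 0.2, log_base = exp(1)) {
  stopifnot(inherits(subbands, "tqwt_subbands"))
  bands <- c(subbands$details, list(subbands$approximation))
  nb <- length(bands)
  vals <- c(
    vapply(bands, entropy_le, numeric(1), log_base = log_base),
    vapply(bands, entropy_ll2, numeric(1), log_base = log_base),
    vapply(bands, entropy_sure, numeric(1), eps = eps),
    vapply(bands, entropy_th, numeric(1), eps = eps)
  )
  names(vals) <- feature_names(subbands$params$J)
  bad <- which(!is.finite(vals))
  if (length(bad) > 0L) {
    stop("numeric error: non-finite entropy for feature ",
         names(vals)[bad[1L]], call. = FALSE)
  }
  vals
}

#' Feature names for a J-level decomposition
#'
#' @param J Number of detail levels.
#' @return Character vector of length `4 * (J + 1)`, entropy-major order.
#' @export
feature_names <- function(J) {
  bands <- c(sprintf("D%02d", seq_len(J)), "A")
  as.vector(vapply(c("LE", "LL2", "SURE", "TH"),
                   function(e) paste0(e, "_", bands),
                   character(J + 1L)))
}
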