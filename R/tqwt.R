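#' TQWT parameter design
#'
#' Derives the filter-bank scaling parameters of the tunable Q-factor
#' wavelet transform from the user-facing controls: the Q-factor `Q`
#' (oscillation count; ratio of a subband's centre frequency to its
#' bandwidth), the oversampling rate `r` (redundancy; overlap between
#' adjacent subband responses) and the number of decomposition levels `J`.
#' The low-pass and high-pass scaling factors follow
#' `beta = 2 / (Q + 1)` and `alpha = 1 - beta / r`, so that
#' `Q = (2 - beta) / beta` and `r = beta / (1 - alpha)` hold exactly.
#'
#' @param Q Q-factor, >= 1 (Q = 1 gives the least oscillatory wavelet).
#' @param r Oversampling rate, > 1.
#' @param J Number of decomposition levels (positive integer).
#' @return A `tqwt_params` object with fields `Q`, `r`, `J`, `alpha`,
#'   `beta`.
#' @examples
#' p <- tqwt_params(3, 3, 26)
#' p$beta            # 0.5
#' (2 - p$beta) / p$beta  # recovers Q
#' @export
tqwt_params <- function(Q, r, J) {
  if (!is.numeric(Q) || length(Q) != 1L || Q < 1) {
    stop("design error: 'Q' must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 1) {
    stop("design error: 'r' must be a single number > 1", call. = FALSE)
  }
  J <- as.integer(J)
  if (length(J) != 1L || is.na(J) || J < 1L) {
    stop("design error: 'J' must be a positive integer", call. = FALSE)
  }
  beta <- 2 / (Q + 1)
  alpha <- 1 - beta / r
  if (alpha <= 0 || alpha >= 1) {
    stop("design error: low-pass scaling alpha = ", alpha,
         " outside (0, 1)", call. = FALSE)
  }
  if (alpha + beta <= 1) {
    stop("design error: alpha + beta must exceed 1 for a non-degenerate ",
         "transition band", call. = FALSE)
  }
  structure(list(Q = Q, r = r, J = J, alpha = alpha, beta = beta),
            class = "tqwt_params")
}

#' @export
print.tqwt_params <- function(x, ...) {
  cat(sprintf("<tqwt_params> Q = %g, r = %g, J = %d (alpha = %.6g, beta = %.6g)\n",
              x$Q, x$r, x$J, x$alpha, x$beta))
  invisible(x)
}

#' Power-complementary transition function
#'
#' The 2*pi-periodic function shaping the filter transition bands: the
#' frequency response of the Daubechies filter with two vanishing moments,
#' `theta(omega) = 0.5 * (1 + cos(omega)) * sqrt(2 - cos(omega))`.
#' It satisfies `theta(omega)^2 + theta(pi - omega)^2 = 1`, which is what
#' makes the analysis/synthesis bank perfectly reconstructing.
#'
#' @param omega Radian frequencies in `[0, pi]` (vectorised).
#' @return Values in `[0, 1]`.
#' @export
tqwt_theta <- function(omega) {
  if (any(omega < 0 | omega > pi)) {
    stop("domain error: 'omega' must lie in [0, pi]", call. = FALSE)
  }
  0.5 * (1 + cos(omega)) * sqrt(2 - cos(omega))
}

#' Maximum admissible decomposition depth
#'
#' The deepest level for which every subband still spans enough DFT bins
#' for the transition-band filters: `Jmax = floor(log(beta * n / 8) /
#' log(1 / alpha))`.  For a 20 s, 512 Hz record after first differencing
#' (n = 10239) at Q = 3, r = 3 this gives 35.
#'
#' @param n Signal length in samples (>= 4).
#' @param Q,r TQWT controls, see [tqwt_params()].
#' @return Integer maximum level, >= 1.
#' @examples
#' tqwt_max_levels(10239, Q = 3, r = 3)
#' @export
tqwt_max_levels <- function(n, Q = 3, r = 3) {
  if (!is.numeric(n) || length(n) != 1L || n < 4) {
    stop("value error: 'n' must be a single length >= 4", call. = FALSE)
  }
  beta <- 2 / (Q + 1)
  alpha <- 1 - beta / r
  if (alpha <= 0 || alpha >= 1 || r <= 1) {
    stop("design error: invalid (Q, r)", call. = FALSE)
  }
  J <- floor(log(beta * n / 8) / log(1 / alpha))
  if (!is.finite(J) || J < 1) {
    stop("value error: signal of length ", n,
         " too short for even one level at Q = ", Q, ", r = ", r, call. = FALSE)
  }
  as.integer(J)
}

# Stage plan: realized even lengths for each analysis stage, computed from
# the (padded, even) input length so rounding does not accumulate.
# Returns a data.frame with one row per level: n_in, n0 (low-pass out),
# n1 (high-pass out).
tqwt_stage_plan <- function(N, alpha, beta, J) {
  n_in <- integer(J)
  n0 <- integer(J)
  n1 <- integer(J)
  cur <- N
  for (j in seq_len(J)) {
    N0 <- 2L * as.integer(round(alpha^j * N / 2))
    N1 <- 2L * as.integer(round(beta * alpha^(j - 1) * N / 2))
    if (N1 < 4L) N1 <- 4L
    if (N1 > cur) N1 <- cur
    # keep the transition band non-negative and the low-pass shrinking
    if (N0 < cur - N1 + 2L) N0 <- cur - N1 + 2L
    if (N0 > cur) N0 <- cur
    if (N0 < 4L) {
      stop("level error: level ", j, " leaves only ", N0,
           " low-pass samples; reduce J", call. = FALSE)
    }
    n_in[j] <- cur
    n0[j] <- N0
    n1[j] <- N1
    cur <- N0
  }
  data.frame(level = seq_len(J), n_in = n_in, n0 = n0, n1 = n1)
}

# One analysis stage in the DFT domain (unitary convention).  X is the
# length-N DFT of the current low-pass branch; returns the length-N0
# low-pass and length-N1 high-pass DFTs.  All lengths even.
tqwt_afb <- function(X, N0, N1) {
  N <- length(X)
  P <- (N - N1) %/% 2L                 # pass-band bins of the low-pass
  Tb <- (N0 + N1 - N) %/% 2L - 1L      # transition-band bins
  if (Tb > 0L) {
    v <- (1:Tb) * pi / (Tb + 1)
    trans <- 0.5 * (1 + cos(v)) * sqrt(2 - cos(v))
  } else {
    trans <- numeric(0)
  }
  V0 <- complex(N0)
  V1 <- complex(N1)
  V0[1L] <- X[1L]
  if (P > 0L) {
    k <- 1:P
    V0[1L + k] <- X[1L + k]
    V0[N0 + 1L - k] <- X[N + 1L - k]
  }
  if (Tb > 0L) {
    t <- 1:Tb
    V0[1L + P + t] <- X[1L + P + t] * trans
    V0[N0 + 1L - P - t] <- X[N + 1L - P - t] * trans
    V1[1L + t] <- X[1L + P + t] * rev(trans)
    V1[N1 + 1L - t] <- X[N + 1L - P - t] * rev(trans)
  }
  hp <- N1 %/% 2L - 1L                 # high-pass full-pass bins
  if (hp >= Tb + 1L) {
    m <- (Tb + 1L):hp
    V1[1L + m] <- X[1L + P + m]
    V1[N1 + 1L - m] <- X[N + 1L - P - m]
  }
  V1[N1 %/% 2L + 1L] <- X[N %/% 2L + 1L]   # input Nyquist lands in V1
  list(V0 = V0, V1 = V1)
}

# One synthesis stage: exact inverse of tqwt_afb.
tqwt_sfb <- function(V0, V1, N) {
  N0 <- length(V0)
  N1 <- length(V1)
  P <- (N - N1) %/% 2L
  Tb <- (N0 + N1 - N) %/% 2L - 1L
  if (Tb > 0L) {
    v <- (1:Tb) * pi / (Tb + 1)
    trans <- 0.5 * (1 + cos(v)) * sqrt(2 - cos(v))
  } else {
    trans <- numeric(0)
  }
  X <- complex(N)
  X[1L] <- V0[1L]
  if (P > 0L) {
    k <- 1:P
    X[1L + k] <- V0[1L + k]
    X[N + 1L - k] <- V0[N0 + 1L - k]
  }
  if (Tb > 0L) {
    t <- 1:Tb
    X[1L + P + t] <- V0[1L + P + t] * trans + V1[1L + t] * rev(trans)
    X[N + 1L - P - t] <- V0[N0 + 1L - P - t] * trans + V1[N1 + 1L - t] * rev(trans)
  }
  hp <- N1 %/% 2L - 1L
  if (hp >= Tb + 1L) {
    m <- (Tb + 1L):hp
    X[1L + P + m] <- V1[1L + m]
    X[N + 1L - P - m] <- V1[N1 + 1L - m]
  }
  X[N %/% 2L + 1L] <- V1[N1 %/% 2L + 1L]
  X
}

udft <- function(x) stats::fft(x) / sqrt(length(x))
uidft <- function(X) Re(stats::fft(X, inverse = TRUE)) / sqrt(length(X))

#' Tunable Q-factor wavelet decomposition
#'
#' Splits a signal into `J` detail subbands plus one approximation with an
#' oversampled two-channel filter bank applied recursively to the low-pass
#' branch.  Each stage applies the designed low-/high-pass frequency
#' responses and resamples in the DFT domain, with subband lengths rounded
#' to even integers; odd-length inputs are zero-padded by one sample
#' (recorded and undone on reconstruction).  The unitary DFT convention is
#' used, so the subband energies of the analysis partition the signal
#' energy exactly.
#'
#' @param signal An [eeg_signal()] or numeric vector.
#' @param params A [tqwt_params()] object; alternatively pass `Q`, `r`,
#'   `J` directly.
#' @param Q,r,J Used only when `params` is missing.
#' @return A `tqwt_subbands` object: list with `details` (list of `J`
#'   coefficient vectors, detail 1 = highest frequency), `approximation`,
#'   `params`, `n_original`, `fs`.
#' @examples
#' s <- sin(2 * pi * 10 * (0:511) / 512)
#' w <- tqwt_decompose(s, Q = 2, r = 2, J = 4)
#' length(w$details)
#' @export
tqwt_decompose <- function(signal, params = NULL, Q = 3, r = 3, J = 3) {
  if (is.null(params)) params <- tqwt_params(Q, r, J)
  stopifnot(inherits(params, "tqwt_params"))
  fs <- attr(signal, "fs")
  if (is.null(fs)) fs <- NA_real_
  x <- as.numeric(signal)
  n_original <- length(x)
  jmax <- tqwt_max_levels(n_original, params$Q, params$r)
  if (params$J > jmax) {
    stop("level error: J = ", params$J, " exceeds the maximum ", jmax,
         " for a signal of length ", n_original, call. = FALSE)
  }
  if (n_original %% 2L == 1L) x <- c(x, 0)     # radix-2 stages need even length
  N <- length(x)
  plan <- tqwt_stage_plan(N, params$alpha, params$beta, params$J)
  X <- udft(x)
  details <- vector("list", params$J)
  for (j in seq_len(params$J)) {
    ab <- tqwt_afb(X, plan$n0[j], plan$n1[j])
    details[[j]] <- uidft(ab$V1)
    X <- ab$V0
  }
  structure(list(details = details,
                 approximation = uidft(X),
                 params = params,
                 n_original = n_original,
                 fs = fs),
            class = "tqwt_subbands")
}

#' @export
print.tqwt_subbands <- function(x, ...) {
  cat(sprintf("<tqwt_subbands> %d details + 1 approximation (Q = %g, r = %g, J = %d, n = %d)\n",
              length(x$details), x$params$Q, x$params$r, x$params$J, x$n_original))
  invisible(x)
}

#' Number of subbands (J details + 1 approximation)
#' @param x A `tqwt_subbands` object.
#' @return Integer count.
#' @export
n_subbands <- function(x) {
  stopifnot(inherits(x, "tqwt_subbands"))
  length(x$details) + 1L
}

#' Inverse tunable Q-factor wavelet transform
#'
#' Runs the synthesis filter bank over a subband set, reproducing the
#' analysed signal to floating-point accuracy when all subbands are kept.
#' Zeroing subbands before calling gives band-limited reconstructions.
#'
#' @param subbands A `tqwt_subbands` object from [tqwt_decompose()], whose
#'   coefficient vectors may have been modified (same lengths).
#' @return An [eeg_signal()] (or plain numeric when the analysed signal
#'   carried no sampling rate) of length `n_original`.
#' @export
tqwt_reconstruct <- function(subbands) {
  stopifnot(inherits(subbands, "tqwt_subbands"))
  p <- subbands$params
  J <- p$J
  if (length(subbands$details) != J) {
    stop("shape error: expected ", J, " detail subbands, got ",
         length(subbands$details), call. = FALSE)
  }
  N <- subbands$n_original + subbands$n_original %% 2L
  plan <- tqwt_stage_plan(N, p$alpha, p$beta, J)
  if (length(subbands$approximation) != plan$n0[J]) {
    stop("shape error: approximation has length ",
         length(subbands$approximation), ", expected ", plan$n0[J], call. = FALSE)
  }
  bad <- which(lengths(subbands$details) != plan$n1)
  if (length(bad) > 0L) {
    stop("shape error: detail ", bad[1L], " has length ",
         lengths(subbands$details)[bad[1L]], ", expected ",
         plan$n1[bad[1L]], call. = FALSE)
  }
  X <- udft(subbands$approximation)
  for (j in rev(seq_len(J))) {
    V1 <- udft(subbands$details[[j]])
    X <- tqwt_sfb(X, V1, plan$n_in[j])
  }
  out <- uidft(X)[seq_len(subbands$n_original)]
  if (is.finite(subbands$fs)) out <- eeg_signal(out, subbands$fs)
  out
}

#' Subband centre frequencies and bandwidths
#'
#' For detail level `j` the designed response is centred at
#' `fc = alpha^(j-1) * (2 - beta) * fs / 4` with bandwidth
#' `bw = alpha^(j-1) * beta * fs / 4`, so `fc / bw = (2 - beta) / beta = Q`
#' at every level.  The approximation row reports its low-pass band
#' `[0, alpha^J * fs / 2]` as `fc = alpha^J * fs / 4`,
#' `bw = alpha^J * fs / 2`.
#'
#' @param params A [tqwt_params()] object.
#' @param fs Sampling rate in Hz (default 512).
#' @return A tibble with columns `subband` (1..J+1), `type`, `fc_hz`,
#'   `bw_hz`.
#' @export
subband_frequencies <- function(params, fs = 512) {
  stopifnot(inherits(params, "tqwt_params"))
  J <- params$J
  a <- params$alpha
  b <- params$beta
  j <- seq_len(J)
  fc <- a^(j - 1) * (2 - b) * fs / 4
  bw <- a^(j - 1) * b * fs / 4
  tibble::tibble(
    subband = c(j, J + 1L),
    type = c(rep("detail", J), "approximation"),
    fc_hz = c(fc, a^J * fs / 4),
    bw_hz = c(bw, a^J * fs / 2)
  )
}
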