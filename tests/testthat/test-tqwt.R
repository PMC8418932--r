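test_that("parameter design inverts the Q/r definitions", {
  p <- tqwt_params(3, 3, 5)
  expect_equal(p$beta, 0.5)
  expect_equal(p$alpha, 5 / 6)
  p <- tqwt_params(2, 2, 5)
  expect_equal(p$beta, 2 / 3)
  expect_equal(p$alpha, 2 / 3)
  for (Q in c(1, 1.5, 2, 3, 5, 10)) for (r in c(1.5, 2, 3, 5)) {
    p <- tqwt_params(Q, r, 2)
    expect_equal((2 - p$beta) / p$beta, Q, tolerance = 1e-12)
    expect_equal(p$beta / (1 - p$alpha), r, tolerance = 1e-12)
    expect_gt(p$alpha + p$beta, 1)
  }
  expect_error(tqwt_params(0.5, 3, 5), "design error")
  expect_error(tqwt_params(3, 1, 5), "design error")
  expect_error(tqwt_params(3, 3, 0), "design error")
})

test_that("transition function hits its endpoints and midpoint", {
  expect_equal(tqwt_theta(0), 1)
  expect_equal(tqwt_theta(pi), 0)
  expect_equal(tqwt_theta(pi / 2), sqrt(2) / 2, tolerance = 1e-5)
  expect_error(tqwt_theta(-0.1), "domain error")
  expect_error(tqwt_theta(pi + 0.1), "domain error")
})

test_that("theta is power-complementary on a dense grid", {
  w <- seq(0, pi, length.out = 10001)
  expect_lt(max(abs(tqwt_theta(w)^2 + tqwt_theta(pi - w)^2 - 1)), 1e-12)
})

test_that("the max-level rule reproduces the 20 s record depth and stays feasible", {
  expect_identical(tqwt_max_levels(10239, 3, 3), 35L)
  expect_identical(tqwt_max_levels(10240, 3, 3), 35L)
  expect_error(tqwt_max_levels(5, 3, 3), "too short")
  # iterative feasibility: decomposing at exactly Jmax must succeed with
  # perfect reconstruction for every (Q, r) on moderate lengths
  set.seed(3)
  for (Q in c(1.5, 2, 3, 5)) for (r in c(2, 3, 4)) for (n in c(300, 1024, 4096)) {
    jm <- tqwt_max_levels(n, Q, r)
    s <- rnorm(n)
    w <- tqwt_decompose(s, tqwt_params(Q, r, jm))
    expect_lt(rel_l2_error(as.numeric(tqwt_reconstruct(w)), s), 1e-8)
    expect_error(tqwt_decompose(s, tqwt_params(Q, r, jm + 1L)), "level error")
  }
})

test_that("a DC signal passes untouched into the approximation", {
  w <- tqwt_decompose(rep(2.5, 512), tqwt_params(3, 3, 10))
  expect_lt(max(abs(unlist(w$details))), 1e-10)
  # unitary convention: subband energies partition the signal energy
  expect_equal(sum(w$approximation^2), sum(rep(2.5, 512)^2), tolerance = 1e-10)
})

test_that("a near-Nyquist tone concentrates in detail 1", {
  s <- cos(2 * pi * 0.49 * (0:1023))
  w <- tqwt_decompose(s, tqwt_params(3, 3, 8))
  e <- c(vapply(w$details, function(d) sum(d^2), numeric(1)), sum(w$approximation^2))
  expect_gt(e[1] / sum(e), 0.95)
})

test_that("analysis-synthesis is a perfect-reconstruction pair", {
  set.seed(9)
  for (n in c(100, 1023)) {
    s <- rnorm(n)
    for (J in c(1, 3)) {
      w <- tqwt_decompose(s, tqwt_params(3, 3, J))
      expect_length(w$details, J)
      got <- as.numeric(tqwt_reconstruct(w))
      expect_length(got, n)
      expect_lt(rel_l2_error(got, s), 1e-8)
      # Parseval under the unitary convention
      expect_equal(sum(unlist(w$details)^2) + sum(w$approximation^2),
                   sum(s^2), tolerance = 1e-10)
    }
  }
})

test_that("the transform is linear", {
  set.seed(4)
  n <- 400
  s <- rnorm(n); t <- rnorm(n)
  p <- tqwt_params(2, 3, 6)
  ws <- tqwt_decompose(s, p); wt <- tqwt_decompose(t, p)
  wc <- tqwt_decompose(1.7 * s - 0.4 * t, p)
  for (j in seq_len(6)) {
    expect_equal(wc$details[[j]], 1.7 * ws$details[[j]] - 0.4 * wt$details[[j]],
                 tolerance = 1e-10)
  }
  expect_equal(wc$approximation, 1.7 * ws$approximation - 0.4 * wt$approximation,
               tolerance = 1e-10)
})

test_that("reconstruction handles degenerate and band-limited subband sets", {
  set.seed(5)
  s <- rnorm(600)
  w <- tqwt_decompose(s, tqwt_params(3, 3, 8))
  # all-zero subbands reconstruct to zero
  w0 <- w
  w0$details <- lapply(w0$details, function(d) d * 0)
  w0$approximation <- w0$approximation * 0
  expect_equal(max(abs(as.numeric(tqwt_reconstruct(w0)))), 0)
  # zeroing the details leaves a low-pass signal: spectral energy above the
  # approximation band is a negligible fraction of the total
  wl <- w
  wl$details <- lapply(wl$details, function(d) d * 0)
  lp <- as.numeric(tqwt_reconstruct(wl))
  spec <- Mod(fft(lp))^2
  half <- 1:(length(lp) %/% 2)
  cutoff <- w$params$alpha^8 * pi
  omega <- 2 * pi * (half - 1) / length(lp)
  expect_lt(sum(spec[half][omega > cutoff]) / sum(spec[half]), 0.01)
  # inconsistent subband lengths are a shape error
  wbad <- w
  wbad$details[[2]] <- wbad$details[[2]][-1]
  expect_error(tqwt_reconstruct(wbad), "shape error")
})

test_that("subband frequencies keep the designed Q and decrease strictly", {
  p <- tqwt_params(3, 3, 12)
  sf <- subband_frequencies(p, fs = 512)
  expect_equal(nrow(sf), 13)
  det <- sf[sf$type == "detail", ]
  expect_equal(det$fc_hz / det$bw_hz, rep(3, 12), tolerance = 1e-9)
  expect_true(all(diff(sf$fc_hz) < 0))
  # top band: detail 1 sits between (1 - beta) * fs/2 and fs/2
  expect_gte(det$fc_hz[1], (1 - p$beta) * 512 / 2)
  expect_lte(det$fc_hz[1], 512 / 2)
})

test_that("subband count is J + 1", {
  set.seed(6)
  s <- rnorm(900)
  for (J in c(1L, 4L, 9L)) {
    expect_identical(n_subbands(tqwt_decompose(s, tqwt_params(2, 2, J))), J + 1L)
  }
})
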