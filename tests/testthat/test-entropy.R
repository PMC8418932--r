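test_that("log-energy entropy follows its definition and conventions", {
  expect_equal(entropy_le(1), 0)
  expect_equal(entropy_le(c(0, 0, 0)), 0)     # zero-sample terms contribute 0
  expect_equal(entropy_le(c(2, 0.5)), 0)      # log(4) + log(1/4) in any base
  expect_equal(entropy_le(c(2, 4)), log(4) + log(16))
  expect_equal(entropy_le(c(2, 4), log_base = 2), 2 + 4)
  expect_error(entropy_le(numeric(0)), "empty")
})

test_that("LL2 entropy is the log of total energy with a guarded zero case", {
  expect_equal(entropy_ll2(c(1, 0, 0)), 0)
  expect_equal(entropy_ll2(c(3, 4)), log(25))
  expect_warning(z <- entropy_ll2(c(0, 0)), "all-zero")
  expect_equal(z, 0)
  # scaling identity
  set.seed(8)
  s <- rnorm(30)
  expect_equal(entropy_ll2(3 * s), entropy_ll2(s) + 2 * log(3))
})

test_that("SURE entropy counts, clips and reduces to closed forms", {
  expect_equal(entropy_sure(c(0, 0), eps = 0.2), 0)
  expect_equal(entropy_sure(c(0.1, 0.3, 0.5), eps = 0.2), 2.09)
  # all coefficients far above eps: n + n * eps^2
  s <- c(5, -7, 9, 11)
  expect_equal(entropy_sure(s, eps = 0.2), 4 + 4 * 0.04)
  # ties at eps count as below threshold
  expect_equal(entropy_sure(c(0.2, 0.2), eps = 0.2), 0 + 2 * 0.04)
  expect_error(entropy_sure(c(1, 2), eps = -1), "positive")
})

test_that("threshold entropy counts magnitudes above eps", {
  expect_equal(entropy_th(c(0.1, 0.3, 0.5), eps = 0.2), 2)
  expect_equal(entropy_th(c(0, 0, 0), eps = 0.2), 0)
  expect_equal(entropy_th(c(-0.5, 0.5), eps = 0.2), 2)  # absolute value
  expect_equal(entropy_th(c(0.2), eps = 0.2), 0)        # tie goes below
  set.seed(10)
  s <- rnorm(50)
  expect_gte(entropy_th(s), 0)
  expect_lte(entropy_th(s), 50)
})

test_that("entropies are permutation invariant and threshold-monotone", {
  set.seed(11)
  s <- rnorm(40)
  p <- sample(40)
  expect_equal(entropy_le(s[p]), entropy_le(s))
  expect_equal(entropy_ll2(s[p]), entropy_ll2(s))
  expect_equal(entropy_sure(s[p]), entropy_sure(s))
  expect_equal(entropy_th(s[p]), entropy_th(s))
  # pushing one coefficient's magnitude past eps cannot decrease TH or SURE
  s2 <- s
  i <- which.min(abs(s))
  s2[i] <- 5
  expect_gte(entropy_th(s2), entropy_th(s))
  expect_gte(entropy_sure(s2), entropy_sure(s))
})

test_that("the feature vector stacks four entropy blocks over J + 1 subbands", {
  set.seed(12)
  w <- tqwt_decompose(rnorm(300), tqwt_params(3, 3, 1))
  v <- subband_entropies(w)
  expect_length(v, 8)                       # 4 * (J + 1) at J = 1
  expect_identical(names(v),
                   c("LE_D01", "LE_A", "LL2_D01", "LL2_A",
                     "SURE_D01", "SURE_A", "TH_D01", "TH_A"))
  # block bookkeeping: permuting the subbands permutes all four blocks alike
  w5 <- tqwt_decompose(rnorm(300), tqwt_params(3, 3, 5))
  v5 <- subband_entropies(w5)
  perm <- c(3, 1, 5, 2, 4)
  wp <- w5
  wp$details <- w5$details[perm]
  vp <- subband_entropies(wp)
  for (blk in c("LE", "LL2", "SURE", "TH")) {
    orig <- v5[sprintf("%s_D%02d", blk, 1:5)]
    shuf <- vp[sprintf("%s_D%02d", blk, 1:5)]
    expect_equal(unname(shuf), unname(orig[perm]))
    expect_equal(vp[paste0(blk, "_A")], v5[paste0(blk, "_A")])
  }
})

test_that("feature tables carry record ids, labels and all feature columns", {
  expect_equal(nrow(small_features), 20)
  expect_equal(ncol(small_features), 2 + 4 * 6)   # J = 5
  expect_equal(sum(small_features$label == "focal"), 10)
  expect_true(all(is.finite(as.matrix(small_features[, -(1:2)]))))
})

test_that("Kruskal-Wallis screening separates what should separate", {
  # duplicated class distributions: no group effect, p = 1
  x <- tibble::tibble(record = sprintf("r%d", 1:8),
                      label = rep(c("focal", "nonfocal"), each = 4),
                      f1 = rep(c(1, 2, 3, 4), 2))
  ks <- kws_screen(x)
  expect_equal(ks$p_value, 1, tolerance = 1e-12)
  expect_false(ks$keep)
  # perfect separation at n = 20 per class
  y <- tibble::tibble(record = sprintf("r%d", 1:40),
                      label = rep(c("focal", "nonfocal"), each = 20),
                      f1 = c(seq(0, 1, length.out = 20), seq(5, 6, length.out = 20)))
  expect_lt(kws_screen(y)$p_value, 1e-6)
  # single class is an error
  z <- x[x$label == "focal", ]
  expect_error(kws_screen(z), "both classes")
})

test_that("Kruskal-Wallis p-values agree with a label-permutation null", {
  set.seed(13)
  n <- 8
  vals <- c(rnorm(n), rnorm(n, mean = 1))
  lab <- rep(c("focal", "nonfocal"), each = n)
  ft <- tibble::tibble(record = sprintf("r%d", 1:(2 * n)), label = lab, f1 = vals)
  p_kw <- kws_screen(ft)$p_value
  kw_stat <- function(v, g) unname(stats::kruskal.test(v, factor(g))$statistic)
  obs <- kw_stat(vals, lab)
  perms <- replicate(4000, kw_stat(vals, sample(lab)))
  p_perm <- mean(perms >= obs - 1e-12)
  # chi-squared approximation vs Monte-Carlo null
  expect_lt(abs(p_kw - p_perm), 0.05)
})

test_that("feature masks apply by vector, name and screening result", {
  cols <- setdiff(names(small_features), c("record", "label"))
  m <- rep(0, length(cols)); m[c(1, 5)] <- 1
  sub <- apply_mask(small_features, m)
  expect_identical(setdiff(names(sub), c("record", "label")), cols[c(1, 5)])
  sub2 <- apply_mask(small_features, cols[c(1, 5)])
  expect_identical(sub, sub2)
  expect_error(apply_mask(small_features, rep(0, length(cols))), "no features")
  expect_error(apply_mask(small_features, c("nope")), "unknown feature")
})
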