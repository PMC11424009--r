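test_that("rmcorr recovers a common slope from parallel lines", {
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  sub <- rep(c("s1", "s2"), each = 4)
  y <- 2 * x + ifelse(sub == "s1", 5, -3)
  out <- rmcorr(sub, x, y)
  expect_equal(out$slope, 2, tolerance = 1e-10)
  expect_equal(out$r, 1, tolerance = 1e-10)
  expect_equal(out$df, 8 - 2 - 1)
})

test_that("rmcorr matches an independent normal-equations ANCOVA", {
  set.seed(42)
  n_sub <- 5; n_obs <- 6
  sub <- rep(seq_len(n_sub), each = n_obs)
  x <- stats::rnorm(n_sub * n_obs)
  y <- 0.7 * x + rep(stats::rnorm(n_sub, sd = 2), each = n_obs) +
    stats::rnorm(n_sub * n_obs, sd = 0.5)
  out <- rmcorr(sub, x, y)
  # oracle: within-subject centering reduces the ANCOVA to simple regression
  xc <- x - stats::ave(x, sub)
  yc <- y - stats::ave(y, sub)
  slope_o <- sum(xc * yc) / sum(xc^2)
  resid <- yc - slope_o * xc
  ss_err <- sum(resid^2)
  ss_x <- sum((slope_o * xc)^2)
  r_o <- sign(slope_o) * sqrt(ss_x / (ss_x + ss_err))
  expect_equal(out$slope, slope_o, tolerance = 1e-10)
  expect_equal(out$r, r_o, tolerance = 1e-10)
})

test_that("rmcorr null p-values are calibrated (type-I error near alpha)", {
  set.seed(7)
  rejections <- vapply(seq_len(1000), function(i) {
    sub <- rep(1:4, each = 5)
    x <- stats::rnorm(20)
    y <- rep(stats::rnorm(4, sd = 3), each = 5) + stats::rnorm(20)
    rmcorr(sub, x, y)$p_value < 0.05
  }, logical(1))
  # binomial 95% band around 0.05 at n = 1000: [0.037, 0.064]
  expect_gt(mean(rejections), qbinom(0.025, 1000, 0.05) / 1000 - 1e-9)
  expect_lt(mean(rejections), qbinom(0.975, 1000, 0.05) / 1000 + 1e-9)
})

test_that("rmcorr drops single-observation subjects with a warning", {
  sub <- c("a", "a", "a", "b", "b", "b", "c")
  x <- c(1, 2, 3, 1, 2, 3, 9)
  y <- c(1, 2, 3, 2, 3, 4, 0)
  expect_warning(out <- rmcorr(sub, x, y), "single observation")
  expect_equal(out$n_subjects, 2L)
})

test_that("identical curve sets give no suprathreshold clusters", {
  set.seed(1)
  a <- matrix(stats::rnorm(5 * 101), 5, 101)
  out <- snpm_paired_1d(a, a + 0, seed = 1)
  expect_equal(nrow(out$clusters), 0)
})

test_that("permutation threshold equals exhaustive enumeration at n = 5", {
  set.seed(3)
  n <- 5; K <- 21
  a <- matrix(stats::rnorm(n * K), n, K)
  b <- a + matrix(stats::rnorm(n * K, sd = 0.5), n, K)
  out <- snpm_paired_1d(a, b, alpha = 0.05)
  expect_equal(out$n_perm_used, 2^5)
  # oracle: enumerate all sign assignments independently
  d <- a - b
  tmax <- apply(as.matrix(expand.grid(rep(list(c(1, -1)), n))), 1, function(s) {
    ds <- d * s
    mcol <- colMeans(ds)
    scol <- apply(ds, 2, stats::sd)
    max(abs(mcol / (scol / sqrt(n))))
  })
  expect_equal(out$threshold, sort(tmax)[ceiling(0.95 * 2^n)])
})

test_that("a localized offset produces one cluster covering that region", {
  set.seed(9)
  n <- 8; K <- 101
  a <- matrix(stats::rnorm(n * K, sd = 0.2), n, K)
  b <- a
  b[, 41:60] <- b[, 41:60] + 5   # large offset on 40-60% of the cycle
  out <- snpm_paired_1d(a, b, seed = 2)
  expect_equal(nrow(out$clusters), 1)
  expect_lte(out$clusters$start_pct, 42)
  expect_gte(out$clusters$end_pct, 58)
  expect_lt(out$clusters$p_value, 0.05)
})

test_that("snpm is invariant to subject reordering", {
  set.seed(5)
  a <- matrix(stats::rnorm(6 * 51), 6, 51)
  b <- a + matrix(stats::rnorm(6 * 51, sd = 0.5), 6, 51)
  o1 <- snpm_paired_1d(a, b)
  perm <- c(3, 1, 6, 2, 5, 4)
  o2 <- snpm_paired_1d(a[perm, ], b[perm, ])
  expect_equal(o1$threshold, o2$threshold)
  expect_equal(o1$t, o2$t)
})

test_that("wilcoxon signed-rank exact p for n = 8 all-positive differences", {
  x <- 1:8 + 0.5
  y <- 1:8 - c(0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 1.2, 1.3)
  out <- wilcoxon_signed_rank(x, y)
  expect_true(out$exact)
  expect_equal(out$p_value, 2 / 2^8)
})

test_that("wilcoxon handles ties-free enumeration and degenerate input", {
  set.seed(8)
  x <- stats::rnorm(6)
  y <- x + stats::rnorm(6)
  out <- wilcoxon_signed_rank(x, y)
  # exhaustive oracle over all sign assignments of the ranked differences
  d <- x - y
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  v_all <- signs %*% rk
  p_oracle <- mean(abs(v_all - sum(rk) / 2) >= abs(v_obs - sum(rk) / 2))
  expect_equal(out$p_value, p_oracle, tolerance = 1e-12)
  expect_warning(out2 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(out2$p_value, 1)
})

test_that("agreement metrics are exact on constructed curves", {
  x <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(agreement_metrics(x, x), tibble::tibble(r = 1, rmse = 0))
  out <- agreement_metrics(x + 0.1, x)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$rmse, 0.1, tolerance = 1e-12)
  # hand-sized example against the direct formulas
  a <- c(1, 2, 4, 3, 5); b <- c(2, 1, 4, 4, 6)
  out2 <- agreement_metrics(a, b)
  expect_equal(out2$r, stats::cor(a, b))
  expect_equal(out2$rmse, sqrt(mean((a - b)^2)))
  expect_warning(agreement_metrics(a, rep(1, 5)), "constant")
})

test_that("on/off timing finds threshold crossings in cycle percent", {
  e <- rep(0, 101); e[21:41] <- 1
  out <- onoff_timing(e)
  expect_equal(out$on_pct, 20)
  expect_equal(out$off_pct, 40)
  expect_equal(nrow(onoff_timing(rep(0, 101))), 0)
  expect_equal(nrow(onoff_timing(e, threshold = 1.01)), 0)
  # two pulses, in order
  e2 <- rep(0, 101); e2[11:21] <- 1; e2[61:81] <- 0.9
  out2 <- onoff_timing(e2)
  expect_equal(nrow(out2), 2)
  expect_true(all(diff(out2$on_pct) > 0))
})
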