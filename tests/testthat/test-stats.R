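test_that("the SNR statistic reproduces hand-computed values", {
  # condition means +1/-1, within-condition trial variance 1, constant in t
  nt <- 16
  arr <- array(NA_real_, c(nt, 1, 1, 4))
  arr[, 1, 1, 1] <- 1 + 1 / sqrt(2)
  arr[, 1, 1, 2] <- 1 - 1 / sqrt(2)
  arr[, 1, 1, 3] <- -1 + 1 / sqrt(2)
  arr[, 1, 1, 4] <- -1 - 1 / sqrt(2)
  rbp <- make_rbp_tensor(arr, seq(-2, 2, length.out = nt), "alpha",
                         c("ext2int", "ext2int", "int2ext", "int2ext"))
  out <- rbp_snr(rbp)
  expect_equal(unname(out$snr_db["alpha", 1]), 10 * log10(2),
               tolerance = 1e-9)
  # scale invariance
  rbp10 <- rbp; rbp10$rbp <- rbp$rbp * 10
  expect_equal(rbp_snr(rbp10)$snr_db, out$snr_db, tolerance = 1e-9)
  # identical condition means -> the -120 dB sentinel
  arr0 <- arr; arr0[, 1, 1, 3:4] <- arr0[, 1, 1, 1:2]
  rbp0 <- make_rbp_tensor(arr0, rbp$time, "alpha", rbp$condition)
  expect_equal(unname(rbp_snr(rbp0)$snr_db["alpha", 1]), -120)
})

test_that("BH adjustment matches hand-worked examples", {
  out <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_equal(out$adjusted, rep(0.04, 4))
  expect_true(all(out$rejected))
  out1 <- fdr_adjust(rep(1, 5))
  expect_equal(out1$adjusted, rep(1, 5))
  expect_false(any(out1$rejected))
  expect_equal(fdr_adjust(0.03)$adjusted, 0.03)
  expect_length(fdr_adjust(numeric(0))$adjusted, 0)
})

test_that("BH rejection sets equal the brute-force step-up oracle", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_adjust(p, q)$rejected, bh_stepup_oracle(p, q))
  }
})

test_that("the vectorized rank-sum test matches wilcox.test", {
  set.seed(12)
  x <- matrix(rnorm(60 * 20), 60)
  y <- matrix(rnorm(60 * 20, mean = 0.3), 60)
  p <- rank_sum_test(x, y)
  ref <- vapply(1:20, function(j)
    wilcox.test(x[, j], y[, j], exact = FALSE, correct = TRUE)$p.value,
    numeric(1))
  expect_equal(p, ref, tolerance = 1e-9)
  # exact path for small samples
  xs <- rnorm(6); ys <- rnorm(7)
  expect_equal(rank_sum_test(xs, ys),
               wilcox.test(xs, ys, exact = TRUE)$p.value, tolerance = 1e-9)
})

test_that("the rank-sum test agrees with a permutation test at small n", {
  set.seed(13)
  xs <- rnorm(7); ys <- rnorm(8, mean = 1)
  p <- rank_sum_test(xs, ys)
  pooled <- c(xs, ys)
  nperm <- 4000
  stat <- function(ix) sum(rank(pooled)[ix])
  obs <- sum(rank(pooled)[1:7])
  mu <- 7 * (7 + 8 + 1) / 2
  cnt <- 0
  for (i in seq_len(nperm)) {
    ix <- sample(15, 7)
    if (abs(stat(ix) - mu) >= abs(obs - mu) - 1e-9) cnt <- cnt + 1
  }
  expect_equal(p, cnt / nperm, tolerance = 0.03)
})

test_that("the continuity rule keeps runs > 100 ms and removes shorter ones", {
  set.seed(14)
  nt <- 40; ntr <- 60
  arr <- array(rnorm(nt * 1 * 2 * 2 * ntr), c(nt, 1, 2, 2 * ntr))
  cond <- rep(c("ext2int", "int2ext"), each = ntr)
  # channel 1: 5-step offset (156 ms > 100 ms); channel 2: 3 steps (94 ms)
  arr[10:14, 1, 1, cond == "ext2int"] <- arr[10:14, 1, 1, cond == "ext2int"] + 3
  arr[10:12, 1, 2, cond == "ext2int"] <- arr[10:12, 1, 2, cond == "ext2int"] + 3
  rbp <- make_rbp_tensor(arr, (seq_len(nt) - 20) * 0.03125, "alpha", cond)
  sig <- channel_significance(rbp)
  expect_true(sig$subjects[[1]]$sig_channel["alpha", 1])
  expect_false(sig$subjects[[1]]$sig_channel["alpha", 2])
  # the surviving mask covers exactly the planted run of channel 1
  expect_equal(which(sig$subjects[[1]]$sig_mask[, 1, 1]), 10:14)
  expect_equal(sig$R_C, 0.5)
  expect_equal(sig$R_S, 1)
})

test_that("network-level significance flags the planted interval only", {
  set.seed(15)
  nt <- 40; ntr <- 30; k <- 24
  arr <- array(rnorm(nt * 1 * k * 2 * ntr, sd = 0.3), c(nt, 1, k, 2 * ntr))
  cond <- rep(c("ext2int", "int2ext"), each = ntr)
  arr[15:25, 1, 1:12, cond == "ext2int"] <-
    arr[15:25, 1, 1:12, cond == "ext2int"] + 2
  rbp <- make_rbp_tensor(arr, (seq_len(nt) - 20) * 0.03125, "alpha", cond)
  out <- network_significance(rbp, list(A = 1:12, B = 13:24), alpha = 0.001)
  expect_true(all(out$masks$A[15:25, 1]))
  expect_false(any(out$masks$A[c(1:12, 28:40), 1]))
  expect_false(any(out$masks$B[, 1]))
  # single-channel networks are declined
  out1 <- network_significance(rbp, list(A = 1), alpha = 0.001)
  expect_match(out1$skipped, "fewer than 2")
})

test_that("common-mean subtraction yields exact mirror residuals", {
  f <- sin(seq(0, 4, length.out = 50))
  g <- cos(seq(0, 4, length.out = 50))
  out <- subtract_common(f, g)
  expect_equal(out$r1 + out$r2, rep(0, 50))
  out2 <- subtract_common(f, -f)
  expect_equal(out2$r1, f)
  out3 <- subtract_common(f, f)
  expect_true(all(out3$r1 == 0) && all(out3$r2 == 0))
})

test_that("crossover timing finds the first in-window crossing with interpolation", {
  time <- seq(-2.3, 2.3, by = 0.03125)
  # residuals +-(t - 0.6): exact linear crossing at 0.6 s
  m1 <- time - 0.6; m2 <- -(time - 0.6)
  expect_equal(crossover_time(m1, m2, time, lowpass_hz = NULL), 0.6,
               tolerance = 1e-9)
  # smoothing keeps the symmetric crossing in place
  expect_equal(crossover_time(m1, m2, time), 0.6, tolerance = 0.04)
  # crossing outside [-0.5, 2] only -> none
  m3 <- time + 0.8; m4 <- -(time + 0.8)
  expect_true(is.na(crossover_time(m3, m4, time, lowpass_hz = NULL)))
  # multiple crossings -> the first (0.3 before 1.2)
  d <- (time - 0.3) * (time - 1.2)
  expect_equal(crossover_time(d / 2, -d / 2, time, lowpass_hz = NULL), 0.3,
               tolerance = 1e-3)
})

test_that("crossover comparison reports the mean lag and is null-calibrated", {
  set.seed(16)
  a <- matrix(0.5 + rnorm(30, sd = 0.05), 1, dimnames = list("hgb", NULL))
  b <- matrix(0.5 + rnorm(30, sd = 0.05), 1, dimnames = list("hgb", NULL))
  out <- compare_crossovers(a, b)
  expect_gt(out$p, 0.05)
  expect_lt(abs(out$mean_diff_ms), 40)
  b2 <- b + 0.22
  out2 <- compare_crossovers(a, b2)
  expect_lt(out2$p_adj, 0.001)
  expect_equal(out2$mean_diff_ms, -220, tolerance = 40)
})
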