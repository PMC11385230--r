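test_that("band splitting isolates a 40 Hz component in the 31-48 Hz band", {
  fs <- 512
  nt <- 4096
  x <- sin(2 * pi * 40 * seq_len(nt) / fs)
  dat <- array(rep(x, 2 * 2), c(nt, 2, 2))
  tr <- make_trial_tensor(dat, fs)
  out <- band_split(tr)
  expect_equal(out[[2]]$order, 17L) # p equals the integer bandwidth
  pw <- vapply(out, function(b) var(b$data[1000:3000, 1, 1]), numeric(1))
  expect_gt(pw[2] / max(pw[-2]), 1e4) # >= 40 dB separation
  # zero trials stay zero
  tr0 <- make_trial_tensor(array(0, c(512, 2, 2)), fs)
  expect_true(all(vapply(band_split(tr0),
                         function(b) all(b$data == 0), logical(1))))
})

test_that("MVAR least squares recovers a known VAR(2)", {
  set.seed(21)
  k <- 3
  A <- array(0, c(k, k, 2))
  A[, , 1] <- diag(0.5, k); A[1, 2, 1] <- 0.3
  A[, , 2] <- -diag(0.2, k)
  dat <- simulate_var(A, 0.5, 256, 60)
  m <- fit_mvar(dat, 2, 512)
  expect_lt(sqrt(mean((m$A - A)^2)), 0.05)
  expect_equal(dim(m$Z), c(k, k))
  # white noise: coefficients stay within the asymptotic null bound
  wn <- array(rnorm(256 * 2 * 30), c(256, 2, 30))
  mw <- fit_mvar(wn, 3, 512)
  expect_lt(max(abs(mw$A)), 3 / sqrt(mw$nobs))
  expect_error(fit_mvar(dat, 0, 512), "at least 1")
})

test_that("the transfer function matches closed forms", {
  # A = 0 -> H = I at every frequency
  m0 <- structure(list(A = array(0, c(3, 3, 1)), Z = diag(3), p = 1,
                       fs = 512), class = "mvar_model")
  H <- transfer_function(m0, c(1, 10, 50))
  for (i in 1:3) expect_equal(H[, , i], diag(3) + 0i)
  # univariate AR(1), a = 0.5: |H(0)| = 1/(1-a) = 2
  m1 <- structure(list(A = array(0.5, c(1, 1, 1)), Z = diag(1), p = 1,
                       fs = 512), class = "mvar_model")
  expect_equal(Mod(transfer_function(m1, 0)[1, 1, 1]), 2)
  # block-diagonal models stay block-diagonal
  A <- array(0, c(4, 4, 1))
  A[1:2, 1:2, 1] <- matrix(c(0.4, 0.1, 0.2, 0.3), 2)
  A[3:4, 3:4, 1] <- matrix(c(0.2, -0.1, 0.1, 0.5), 2)
  mb <- structure(list(A = A, Z = diag(4), p = 1, fs = 512),
                  class = "mvar_model")
  Hb <- transfer_function(mb, 7)[, , 1]
  expect_equal(Mod(Hb[1:2, 3:4]), matrix(0, 2, 2))
  expect_equal(Mod(Hb[3:4, 1:2]), matrix(0, 2, 2))
})

test_that("DTF and PDC normalizations hold to machine precision", {
  set.seed(22)
  dat <- simulate_var(array(c(0.5, 0.3, 0, 0.4), c(2, 2, 1)), 1, 256, 40)
  m <- fit_mvar(dat, 1, 512)
  fr <- seq(1, 120, by = 7)
  D <- dtf(transfer_function(m, fr))
  expect_lt(max(abs(apply(D, c(1, 3), function(r) sum(r^2)) - 1)), 1e-12)
  expect_true(all(D >= 0 & D <= 1))
  P <- pdc(m, fr)
  expect_lt(max(abs(apply(P, c(2, 3), function(cl) sum(cl^2)) - 1)), 1e-12)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("A = 0 yields identity connectivity patterns and zero GGC off-diagonal", {
  m0 <- structure(list(A = array(0, c(3, 3, 2)), Z = diag(3), p = 2,
                       fs = 512), class = "mvar_model")
  fr <- c(5, 20, 80)
  D <- dtf(transfer_function(m0, fr))
  P <- pdc(m0, fr)
  for (i in seq_along(fr)) {
    expect_equal(D[, , i], diag(3))
    expect_equal(P[, , i], diag(3))
  }
  G <- ggc(m0, transfer_function(m0, fr), fr)
  for (i in seq_along(fr)) expect_equal(G[, , i] - diag(diag(G[, , i])),
                                        matrix(0, 3, 3))
  expect_true(all(G >= 0))
  # non-positive-definite Z errors
  mbad <- m0; mbad$Z <- diag(c(1, -1, 1))
  expect_error(ggc(mbad, transfer_function(mbad, fr), fr), "positive definite")
})

test_that("unidirectional VAR coupling is recovered by DTF, PDC and GGC", {
  set.seed(23)
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(0.5, 0.4, 0, 0.5), 2) # channel 1 drives channel 2
  A[, , 2] <- -diag(0.1, 2)
  dat <- simulate_var(A, 1, 256, 40)
  m <- fit_mvar(dat, 2, 512)
  fr <- 1:40
  H <- transfer_function(m, fr)
  D <- dtf(H); P <- pdc(m, fr); G <- ggc(m, H, fr)
  expect_gt(mean(D[2, 1, ]), mean(D[1, 2, ]))
  expect_gt(mean(P[2, 1, ]), mean(P[1, 2, ]))
  expect_gt(mean(G[2, 1, ]), mean(G[1, 2, ]))
})

test_that("the model-implied spectrum matches the analytic AR(1) spectrum", {
  m1 <- structure(list(A = array(0.6, c(1, 1, 1)), Z = matrix(1), p = 1,
                       fs = 512), class = "mvar_model")
  fr <- c(0, 10, 50, 128)
  S <- mvar_spectrum(m1, fr)
  anly <- 1 / Mod(1 - 0.6 * exp(-2i * pi * fr / 512))^2
  expect_equal(as.numeric(S), anly, tolerance = 1e-12)
})

test_that("sliding windows cover the crop with 33 positions", {
  time <- seq(-4, 4 - 1 / 512, by = 1 / 512)
  w <- ieegswitch:::sliding_windows(time, 512)
  expect_length(w$start, 33)
  expect_equal(w$center_t[1], -2.05)
  expect_equal(w$center_t[33], 1.95)
})

test_that("stationary coupling gives flat z-scored series; PLV self-pair is 1", {
  set.seed(24)
  dat <- array(rnorm(1024 * 2 * 24), c(1024, 2, 24))
  dat[, 2, ] <- dat[, 2, ] + 0.8 * rbind(matrix(0, 4, 24), dat[1:1020, 1, ])
  tr <- make_trial_tensor(dat, 512)
  sc <- sliding_connectivity(tr, list(A = 1, B = 2), "dtf",
                             fit_bands = mvar_fit_bands()[1, , drop = FALSE],
                             crop = c(-0.9, 0.9))
  s <- sc$series[, "alpha", 1, 1]
  expect_equal(mean(s), 0, tolerance = 1e-9) # z-scored along time
  expect_lt(abs(coef(lm(s ~ seq_along(s)))[2]), 2 / length(s))
  # PLV of a channel against itself is exactly 1
  dat2 <- dat; dat2[, 2, ] <- dat[, 1, ]
  pv <- plv(make_trial_tensor(dat2, 512))
  expect_equal(max(abs(pv$plv - 1), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("a fixed inter-channel delay yields PLV 1 in every band", {
  fs <- 512
  nt <- 1024
  set.seed(25)
  # one sinusoid per 2 Hz bin with random phase per trial; channel 2 is a
  # fixed 5-sample delay, i.e. a constant phase lag in every band
  delay <- 5 / fs
  tgrid <- seq_len(nt) / fs
  fgrid <- seq(1, 119, by = 2)
  dat <- array(0, c(nt, 2, 10))
  for (tr in 1:10) {
    ph <- runif(length(fgrid), 0, 2 * pi)
    for (i in seq_along(fgrid)) {
      dat[, 1, tr] <- dat[, 1, tr] + sin(2 * pi * fgrid[i] * tgrid + ph[i])
      dat[, 2, tr] <- dat[, 2, tr] +
        sin(2 * pi * fgrid[i] * (tgrid - delay) + ph[i])
    }
  }
  tt <- make_trial_tensor(dat, fs)
  pv <- plv(tt)
  interior <- abs(pv$time) < 0.6
  expect_gt(min(pv$plv[, interior, , ], na.rm = TRUE), 0.95)
  expect_error(plv(tt, fmax = 300), "Nyquist")
})

test_that("zero coupling leaves the two directed estimates indistinguishable", {
  bm <- data.frame(band = "alpha", lo = 8, hi = 12, amplitude = 0.9,
                   contrast = 0, crossover = 0.5, lag_netb = 0, width = 0.3)
  d_ab <- numeric(30); d_ba <- numeric(30)
  for (i in 1:30) {
    cfg <- gen_config(1, 2, 12, band_modulations = bm, coupling = NULL,
                      seed = 500 + i)
    co <- generate_cohort(cfg)
    tr <- extract_trials(bipolar_reference(co$recordings[[1]]),
                         max_per_condition = 12)
    bs <- band_split(tr, mvar_fit_bands()[1, , drop = FALSE])[[1]]
    idx <- which(tr$time >= -1 & tr$time < 1)
    m <- fit_mvar(bs$data[idx, , bs$condition == "ext2int", drop = FALSE],
                  29, 512)
    D <- dtf(transfer_function(m, 8:12))
    d_ab[i] <- mean(D[3:4, 1:2, ])
    d_ba[i] <- mean(D[1:2, 3:4, ])
  }
  expect_gt(wilcox.test(d_ab, d_ba, paired = TRUE)$p.value, 0.05)
})

test_that("across-subject connectivity statistics detect planted differences", {
  set.seed(26)
  mk <- function(shift) matrix(rnorm(20 * 2, mean = shift), 20, 2,
                               dimnames = list(NULL, c("delta", "alpha")))
  s1 <- lapply(1:15, function(i) mk(0))
  s2 <- lapply(1:15, function(i) { m <- mk(0); m[5:10, 1] <- m[5:10, 1] + 4; m })
  mask <- connectivity_group_stats(list(ext2int = s1, int2ext = s2),
                                   alpha = 0.001)
  expect_true(all(mask[5:10, "delta"]))
  expect_false(any(mask[, "alpha"]))
  # identical series -> nothing significant
  mask0 <- connectivity_group_stats(list(ext2int = s1, int2ext = s1))
  expect_false(any(mask0))
  expect_error(connectivity_group_stats(list(ext2int = s1[1:3],
                                             int2ext = s2[1:3])),
               "at least 5")
})
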