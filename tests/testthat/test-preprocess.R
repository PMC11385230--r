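make_shank_recording <- function(sigs, broken = NULL, fs = 512) {
  k <- length(sigs)
  contacts <- data.frame(name = letters[seq_len(k)], shank = "S",
                         pos = seq_len(k), x = seq_len(k), y = 0, z = 0,
                         broken = FALSE)
  if (!is.null(broken)) contacts$broken[broken] <- TRUE
  ieeg_recording(do.call(cbind, sigs), fs, contacts,
                 data.frame(onset = integer(0), condition = character(0)))
}

test_that("bipolar referencing pairs adjacent contacts deepest-first", {
  a <- sin(seq_len(1000)); b <- cos(seq_len(1000)); c <- rnorm(1000)
  rec <- make_shank_recording(list(a, b, c))
  out <- bipolar_reference(rec)
  expect_equal(ncol(out$signal), 2)
  expect_equal(out$contacts$name, c("a-b", "b-c"))
  expect_equal(out$signal[, 1], a - b)
  expect_equal(out$signal[, 2], b - c)
  expect_equal(out$contacts$x, c(1.5, 2.5))
})

test_that("bipolar referencing cancels common-mode signal", {
  base <- list(rnorm(500), rnorm(500), rnorm(500))
  common <- cumsum(rnorm(500))
  rec1 <- make_shank_recording(base)
  rec2 <- make_shank_recording(lapply(base, `+`, common))
  expect_equal(bipolar_reference(rec1)$signal,
               bipolar_reference(rec2)$signal, tolerance = 1e-12)
  # identical signal on all contacts -> all channels zero
  rec3 <- make_shank_recording(list(common, common, common))
  expect_true(all(bipolar_reference(rec3)$signal == 0))
})

test_that("a broken contact breaks adjacency without skip-pairing", {
  a <- rnorm(500); b <- rnorm(500); c <- rnorm(500)
  rec <- make_shank_recording(list(a, b, c), broken = 2)
  expect_error(bipolar_reference(rec), "no bipolar channels")
  d <- rnorm(500)
  rec4 <- make_shank_recording(list(a, b, c, d), broken = 2)
  out <- bipolar_reference(rec4)
  expect_equal(out$contacts$name, "c-d") # only the intact adjacent pair
})

test_that("a shank with fewer than two usable contacts warns and is skipped", {
  k <- 3
  contacts <- data.frame(name = c("a", "b", "x"), shank = c("S", "S", "T"),
                         pos = c(1, 2, 1), x = 0, y = 0, z = 0,
                         broken = FALSE)
  rec <- ieeg_recording(matrix(rnorm(300), 100, 3), 512, contacts,
                        data.frame(onset = integer(0),
                                   condition = character(0)))
  expect_warning(out <- bipolar_reference(rec), "fewer than 2")
  expect_equal(ncol(out$signal), 1)
})

test_that("the filter chain removes DC, notches 50 Hz and passes 10 Hz", {
  fs <- 512
  t <- seq(0, 30, by = 1 / fs)[-1]
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  rec <- function(x) make_shank_recording(list(x, x * 0), fs = fs)
  # DC offset -> ~0
  dc <- filter_chain(rec(rep(5, length(t))))
  expect_lt(max(abs(dc$signal[mid, 1])), 5 * 1e-6)
  # 50 Hz attenuated by >= 40 dB
  s50 <- filter_chain(rec(sin(2 * pi * 50 * t)))
  amp50 <- sqrt(2 * mean(s50$signal[mid, 1]^2))
  expect_lt(20 * log10(amp50), -40)
  # 10 Hz within +-0.5 dB of unity
  s10 <- filter_chain(rec(sin(2 * pi * 10 * t)))
  amp10 <- sqrt(2 * mean(s10$signal[mid, 1]^2))
  expect_lt(abs(20 * log10(amp10)), 0.5)
  # infeasible notch errors with the band named
  expect_error(filter_chain(rec(t), notches = list(c(250, 260))), "notch")
})

test_that("downsampling decimates exactly and preserves in-band amplitude", {
  fs <- 2048
  t <- seq(0, 20, by = 1 / fs)[-1]
  x <- sin(2 * pi * 30 * t)
  contacts <- data.frame(name = "a", shank = "S", pos = 1, x = 0, y = 0,
                         z = 0, broken = FALSE)
  ev <- data.frame(onset = 8192L, condition = "ext2int")
  rec <- ieeg_recording(matrix(x, ncol = 1), fs, contacts, ev)
  out <- downsample(rec, 512)
  expect_equal(nrow(out$signal), length(t) / 4)
  expect_equal(out$fs, 512)
  expect_equal(out$events$onset, 2048L)
  mid <- seq(round(nrow(out$signal) * 0.3), round(nrow(out$signal) * 0.7))
  amp <- sqrt(2 * mean(out$signal[mid, 1]^2))
  expect_lt(abs(amp - 1), 0.01)
  # identity at the target rate; non-integer ratios error
  expect_identical(downsample(out, 512), out)
  expect_error(downsample(rec, 500), "integer multiple")
})

test_that("trial extraction spans [-4, 4) s with t = 0 at the event", {
  rec <- noise_recording(n_s = 200, k = 2, n_events = 12, seed = 2)
  tr <- extract_trials(rec)
  expect_equal(dim(tr$data)[1], 8 * 512)
  expect_equal(dim(tr$data)[3], 12)
  expect_equal(sum(tr$time < 0), 4 * 512)
  expect_equal(tr$time[4 * 512 + 1], 0)
  # the epoch reproduces the raw samples
  on <- rec$events$onset[1]
  expect_equal(tr$data[, 1, 1], rec$signal[(on - 2048):(on + 2047), 1])
})

test_that("boundary trials are dropped with a warning and empty conditions error", {
  rec <- noise_recording(n_s = 60, k = 1, n_events = 6, seed = 2)
  rec$events$onset[6] <- nrow(rec$signal) - 512L # 1 s from the end
  expect_warning(tr <- extract_trials(rec), "dropped")
  expect_equal(dim(tr$data)[3], 5)
  rec2 <- rec
  rec2$events <- rec2$events[rec2$events$condition == "ext2int", ]
  expect_error(suppressWarnings(extract_trials(rec2)), "int2ext")
})

test_that("epoch rejection masks a planted spike with 100 ms margins", {
  fs <- 512
  rec <- noise_recording(n_s = 120, k = 2, n_events = 8, seed = 4)
  inj <- inject_artifacts(rec, rate = 0, amplitude_sd = 12)
  # plant one 50 ms, 12-SD artifact inside trial 2 manually for determinism
  on <- rec$events$onset[2]
  dur <- round(0.05 * fs)
  seg <- (on + 100):(on + 100 + dur - 1)
  rec$signal[seg, 1] <- rec$signal[seg, 1] + 12 * sd(rec$signal[, 1])
  tr <- extract_trials(rec)
  tr <- reject_epochs(rec, tr, sd_threshold = 6, margin_ms = 100)
  m <- tr$mask[, 1, 2]
  run <- range(which(m))
  expect_equal(diff(run) + 1, dur + 2 * round(0.1 * fs), tolerance = 1)
  # masked interval covers the artifact samples
  t_art <- which(tr$time >= 100 / fs & tr$time < (100 + dur) / fs)
  expect_true(all(m[t_art]))
  # other trials and the clean channel stay unmasked
  expect_false(any(tr$mask[, 2, ]))
  expect_false(any(tr$mask[, 1, -2]))
})

test_that("constant channels yield an empty mask with a warning", {
  rec <- noise_recording(n_s = 60, k = 2, n_events = 4, seed = 6)
  rec$signal[, 2] <- 1
  tr <- extract_trials(rec)
  expect_warning(tr <- reject_epochs(rec, tr), "zero variance")
  expect_false(any(tr$mask[, 2, ]))
})

test_that("recordings round-trip bit-exactly through the binary format", {
  rec <- noise_recording(n_s = 10, k = 2, n_events = 2, seed = 8)
  stem <- file.path(tempdir(), "roundtrip")
  write_recording(rec, stem)
  back <- read_recording(stem)
  expect_identical(back$signal, rec$signal)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$events$onset, rec$events$onset)
  expect_equal(back$events$condition, rec$events$condition)
})
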