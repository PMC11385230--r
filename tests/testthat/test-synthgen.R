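test_that("generation is bit-identical for a fixed seed and differs across subjects", {
  cfg <- gen_config(n_subjects = 2, n_channels_per_network = 2,
                    n_trials_per_condition = 4, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$recordings[[1]]$signal, b$recordings[[1]]$signal)
  expect_identical(a$recordings[[2]]$signal, b$recordings[[2]]$signal)
  expect_false(identical(a$recordings[[1]]$signal, a$recordings[[2]]$signal))
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("config validation rejects infeasible setups", {
  expect_error(gen_config(fs = 200), "twice the highest band edge")
  expect_error(gen_config(trial_span = c(-2, 2)), "2.3")
})

test_that("background spectrum declines as 1/f with the configured slope", {
  cfg <- gen_config(n_subjects = 1, n_channels_per_network = 1,
                    n_trials_per_condition = 4, band_modulations = NULL,
                    background_exponent = 1, seed = 7)
  co <- generate_cohort(cfg)
  rec <- co$recordings[[1]]
  bip <- bipolar_reference(rec)
  sp <- spec.pgram(bip$signal[, 1], spans = 31, taper = 0, plot = FALSE)
  f_hz <- sp$freq * rec$fs
  sel <- f_hz >= 1 & f_hz <= 100
  fit <- lm(log10(sp$spec[sel]) ~ log10(f_hz[sel]))
  slope <- -coef(fit)[2]
  expect_gt(slope, 0.85)
  expect_lt(slope, 1.15)
})

test_that("planted band oscillations raise in-band power", {
  bm <- data.frame(band = "alpha", lo = 8, hi = 12, amplitude = 2,
                   contrast = 0, crossover = 0.5, lag_netb = 0, width = 0.3)
  cfg <- gen_config(1, 1, 4, band_modulations = bm, seed = 3)
  co <- generate_cohort(cfg)
  x <- bipolar_reference(co$recordings[[1]])$signal[, 1]
  inband <- var(zerophase_filter(x, 512, "pass", c(8, 12)))
  ctrl <- var(zerophase_filter(x, 512, "pass", c(18, 22)))
  expect_gt(inband / ctrl, 5)
})

test_that("unidirectional coupling makes the driven group lag the driver", {
  bm <- data.frame(band = "alpha", lo = 8, hi = 12, amplitude = 0.9,
                   contrast = 0, crossover = 0.5, lag_netb = 0, width = 0.3)
  cfg <- gen_config(1, 2, 10, band_modulations = bm,
                    coupling = list(band = c(8, 12), lag = 8, strength = 1.5,
                                    direction = "A->B"), seed = 11)
  co <- generate_cohort(cfg)
  bip <- bipolar_reference(co$recordings[[1]])
  on <- co$recordings[[1]]$events$onset[3]
  seg <- (on - 1500):(on + 1500)
  a <- zerophase_filter(rowMeans(bip$signal[seg, 1:2]), 512, "pass", c(8, 12))
  b <- zerophase_filter(rowMeans(bip$signal[seg, 3:4]), 512, "pass", c(8, 12))
  cc <- ccf(a, b, lag.max = 30, plot = FALSE)
  best <- cc$lag[which.max(abs(cc$acf))]
  # negative lag: the A-group leads; the causal resonator adds its own
  # group delay on top of the planted 8-sample lag
  expect_lt(best, -3)
  expect_gt(best, -30)
})

test_that("artifact injection is logged and rate 0 is the identity", {
  rec <- noise_recording(n_s = 60, k = 2, seed = 5)
  out0 <- inject_artifacts(rec, rate = 0, amplitude_sd = 8)
  expect_identical(out0$recording$signal, rec$signal)
  expect_equal(nrow(out0$log), 0)
  out <- inject_artifacts(rec, rate = 6, amplitude_sd = 10, seed = 9)
  expect_gt(nrow(out$log), 0)
  # logged samples really deviate by ~10 SD
  ev <- out$log[1, ]
  seg <- ev$onset:(ev$onset + ev$duration_s * rec$fs - 1)
  delta <- out$recording$signal[seg, ev$channel] - rec$signal[seg, ev$channel]
  expect_true(all(abs(abs(delta) / sd(rec$signal[, ev$channel]) - 10) < 1e-9))
})

test_that("ground truth and electrode tables serialize to plain formats", {
  cfg <- gen_config(1, 2, 4, seed = 17)
  co <- generate_cohort(cfg)
  gt_path <- file.path(tempdir(), "gt.json")
  write_ground_truth(co$ground_truth, gt_path)
  back <- jsonlite::read_json(gt_path, simplifyVector = FALSE)
  expect_equal(back$seed, 17)
  expect_equal(length(back$subjects[[1]]$crossovers$channel),
               nrow(co$ground_truth$subjects[[1]]$crossovers))
  el_path <- file.path(tempdir(), "electrodes.tsv")
  write_electrodes(co$recordings[[1]]$contacts, el_path)
  el <- read.delim(el_path)
  expect_equal(nrow(el), nrow(co$recordings[[1]]$contacts))
  expect_named(el, c("name", "x", "y", "z"))
})

test_that("zero condition contrast leaves the conditions statistically indistinguishable", {
  bm <- default_band_modulations()
  bm$contrast <- 0
  cfg <- gen_config(1, 2, 20, band_modulations = bm, seed = 13)
  co <- generate_cohort(cfg)
  bip <- filter_chain(bipolar_reference(co$recordings[[1]]))
  rbp <- epoch_rbp(session_rbp(bip), max_per_condition = 20)
  sig <- channel_significance(rbp)
  expect_equal(sum(sig$subjects[[1]]$sig_channel), 0)
})
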