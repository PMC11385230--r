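# Synthetic iEEG cohort generation.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: 512 Hz sampling, 60 trials per switching condition, 1/f-decaying
# background spectra, band-limited oscillations whose amplitude envelopes
# cross over between the two switching conditions near t = 0 s, optional
# lagged cross-group coupling that may reverse at the switch, and rare
# high-amplitude artifacts. Every planted quantity is logged as ground
# truth and is exactly reproducible from (config, seed).

#' Synthetic cohort configuration
#'
#' Defines the study conditions a generated cohort emulates. Two labeled
#' channel groups (`"NetA"`, `"NetB"`) stand in for the default mode and
#' dorsal attention networks.
#'
#' @param n_subjects number of subjects.
#' @param n_channels_per_network bipolar channels per group.
#' @param n_trials_per_condition switch trials per condition (default 60).
#' @param fs sampling rate, Hz (default 512).
#' @param trial_span trial window in seconds relative to the switch
#'   (default `c(-4, 4)`); must contain the analysis crop \[−2.3, 2.3\] s.
#' @param background_exponent 1/f slope of the background power spectrum.
#' @param background_sd standard deviation of the background (µV-like units).
#' @param band_modulations data frame describing planted band-limited
#'   oscillations, one row per band, with columns `band` (name), `lo`, `hi`
#'   (Hz), `amplitude` (envelope baseline, SD units), `contrast`
#'   (condition contrast; the condition-specific amplitude multiplier spans
#'   `1 ± contrast/2` across the transition), `crossover` (s, the time at
#'   which the two conditions' envelopes — and hence band powers — cross),
#'   `lag_netb` (s added to the crossover time of group NetB) and `width`
#'   (s, logistic transition width). See [default_band_modulations()].
#' @param coupling `NULL` or a list with elements `band` (Hz range),
#'   `lag` (samples), `strength` (relative amplitude) and either
#'   `direction` (`"A->B"` or `"B->A"`, constant) or `reversal = TRUE`
#'   (A→B before the switch, B→A after it, in every trial).
#' @param artifact_rate transient artifact rate, events/min (default 0).
#' @param artifact_amplitude artifact amplitude in channel-SD multiples.
#' @param artifact_duration_s artifact duration, s.
#' @param mode `"envelope"` (default; filtered-noise oscillations with
#'   logistic condition-dependent envelopes) or `"ar"` (autoregressive
#'   oscillators with slow sinusoidal envelope modulation, suited to
#'   MVAR spectral-fidelity checks).
#' @param seed master seed; one RNG stream per subject is derived from it.
#' @return A `gen_config` list.
#' @export
gen_config <- function(n_subjects = 1,
                       n_channels_per_network = 5,
                       n_trials_per_condition = 60,
                       fs = 512,
                       trial_span = c(-4, 4),
                       background_exponent = 1,
                       background_sd = 1,
                       band_modulations = default_band_modulations(),
                       coupling = NULL,
                       artifact_rate = 0,
                       artifact_amplitude = 8,
                       artifact_duration_s = 0.05,
                       mode = c("envelope", "ar"),
                       seed = 1) {
  mode <- match.arg(mode)
  if (!is.null(band_modulations) && nrow(band_modulations) > 0) {
    if (fs <= 2 * max(band_modulations$hi))
      stop("sampling rate must exceed twice the highest band edge")
  }
  if (trial_span[1] > -2.3 || trial_span[2] < 2.3)
    stop("trial_span must contain the analysis window [-2.3, 2.3] s")
  structure(list(
    n_subjects = n_subjects,
    n_channels_per_network = n_channels_per_network,
    n_trials_per_condition = n_trials_per_condition,
    fs = fs, trial_span = trial_span,
    background_exponent = background_exponent,
    background_sd = background_sd,
    band_modulations = band_modulations,
    coupling = coupling,
    artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude,
    artifact_duration_s = artifact_duration_s,
    mode = mode, seed = as.integer(seed)
  ), class = "gen_config")
}

#' Default planted band modulations
#'
#' One modulation per analysis band, with crossover times inside the
#' \[−0.5, 2.0\] s search window, a 0.3 s logistic transition and
#' condition contrasts at or above 1 so that planted effects are
#' recoverable by the band-power statistics.
#'
#' @return data frame accepted by [gen_config()].
#' @export
default_band_modulations <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "lgamma", "hgb"),
    lo = c(0.5, 4, 8, 13, 31, 52),
    hi = c(3, 7, 12, 30, 48, 118),
    amplitude = c(0.8, 0.7, 0.9, 0.6, 0.5, 0.6),
    contrast = c(1.2, 1.2, 1.2, 1.0, 1.0, 1.0),
    crossover = c(0.4, 0.5, 0.6, 0.5, 0.5, 0.5),
    lag_netb = 0,
    width = 0.3,
    stringsAsFactors = FALSE
  )
}

# 1/f^a background noise: white Gaussian noise spectrally shaped so that
# power declines as f^(-exponent); rescaled to unit SD.
pink_noise <- function(n, fs, exponent) {
  nfft <- 2^ceiling(log2(n))
  w <- stats::rnorm(nfft)
  f <- abs(fft_freqs(nfft, fs))
  amp <- c(0, f[-1]^(-exponent / 2)) # kill DC
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# Narrow-band Gaussian noise (unit SD): white noise band-passed to [lo, hi].
narrowband_noise <- function(n, fs, lo, hi, order = 6) {
  x <- zerophase_filter(stats::rnorm(n), fs, "pass", c(lo, hi), order)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# Event layout: alternating conditions, onsets snapped to the 16-sample
# (31.25 ms) band-power grid so trial time axes align exactly.
layout_events <- function(config) {
  span <- config$trial_span
  spacing <- (span[2] - span[1]) + 0.25
  n_ev <- 2L * config$n_trials_per_condition
  onset_s <- -span[1] + 0.125 + (seq_len(n_ev) - 1L) * spacing
  onset <- 1L + 16L * as.integer(round(onset_s * config$fs / 16))
  data.frame(
    onset = onset,
    condition = rep(c("ext2int", "int2ext"), length.out = n_ev),
    stringsAsFactors = FALSE
  )
}

# Condition-dependent amplitude multiplier around each event.
# sgn = +1 for ext2int, -1 for int2ext; multiplier spans 1 -/+ contrast/2
# and crosses 1 exactly at the planted crossover time.
envelope_multiplier <- function(n, fs, events, contrast, crossover, width,
                                half_spacing) {
  m <- rep(1, n)
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    sgn <- if (events$condition[i] == "ext2int") 1 else -1
    a <- max(1L, on - half_spacing)
    b <- min(n, on + half_spacing - 1L)
    t_rel <- (a:b - on) / fs
    m[a:b] <- 1 + sgn * contrast * logistic_step(t_rel - crossover, width)
  }
  m
}

subject_seed <- function(master, s) (master + 99991L * s) %% .Machine$integer.max

#' Generate a synthetic iEEG cohort
#'
#' Produces one continuous contact-level recording per subject plus the
#' ground truth of every planted quantity. Each subject's signal is the sum
#' of a 1/f background, band-limited oscillations whose amplitude envelopes
#' follow a sigmoidal condition-dependent crossover at the planted time
#' (per channel group), optional lagged cross-group coupling and optional
#' artifacts. Event rows mark each trial's t = 0 with its condition label.
#'
#' Contacts are laid out so that nearest-neighbor bipolar referencing
#' recovers exactly one planted channel signal per adjacent contact pair
#' while cancelling a shared reference signal: on each shank the
#' shallowest contact carries only the common reference and each deeper
#' contact adds one planted channel signal on top of its neighbor.
#'
#' @param config a [gen_config()] object.
#' @return list with `recordings` (list of [ieeg_recording] objects, one
#'   per subject) and `ground_truth` (list with per-subject planted
#'   crossover tables, coupling description, artifact logs and the seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  recs <- vector("list", config$n_subjects)
  gt <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    out <- generate_subject(config, s)
    recs[[s]] <- out$recording
    gt[[s]] <- out$truth
  }
  list(recordings = recs,
       ground_truth = list(subjects = gt, seed = config$seed,
                           coupling = config$coupling, mode = config$mode))
}

generate_subject <- function(config, s) {
  set.seed(subject_seed(config$seed, s))
  fs <- config$fs
  events <- layout_events(config)
  span <- config$trial_span
  spacing_smp <- as.integer(round(((span[2] - span[1]) + 0.25) * fs))
  n <- max(events$onset) + as.integer(span[2] * fs) + as.integer(fs)
  m <- config$n_channels_per_network
  k <- 2L * m
  group <- rep(c("NetA", "NetB"), each = m)

  sig <- matrix(0, n, k)
  for (ch in seq_len(k))
    sig[, ch] <- config$background_sd * pink_noise(n, fs, config$background_exponent)

  truth_rows <- NULL
  bm <- config$band_modulations
  if (config$mode == "envelope" && !is.null(bm) && nrow(bm) > 0) {
    for (b in seq_len(nrow(bm))) {
      for (g in c("NetA", "NetB")) {
        t_x <- bm$crossover[b] + if (g == "NetB") bm$lag_netb[b] else 0
        mult <- envelope_multiplier(n, fs, events, bm$contrast[b], t_x,
                                    bm$width[b], spacing_smp %/% 2L)
        for (ch in which(group == g)) {
          u <- narrowband_noise(n, fs, bm$lo[b], bm$hi[b])
          sig[, ch] <- sig[, ch] + bm$amplitude[b] * mult * u
          truth_rows <- rbind(truth_rows, data.frame(
            channel = ch, group = g, band = bm$band[b], crossover = t_x,
            stringsAsFactors = FALSE))
        }
      }
    }
  } else if (config$mode == "ar") {
    # Band-limited AR(2) oscillators whose innovation amplitude follows a
    # slow, trial-locked sinusoidal envelope; one oscillator per band.
    if (is.null(bm) || nrow(bm) == 0) stop("ar mode needs band_modulations")
    for (b in seq_len(nrow(bm))) {
      f0 <- (bm$lo[b] + bm$hi[b]) / 2
      # pole radius from the band width so the oscillator's spectral
      # support stays inside its band (half-width resonance bandwidth)
      r <- exp(-pi * (bm$hi[b] - bm$lo[b]) / 2 / fs)
      a1 <- 2 * r * cos(2 * pi * f0 / fs)
      a2 <- -r^2
      for (g in c("NetA", "NetB")) {
        phi <- stats::runif(1, 0, 2 * pi)
        # log-normal amplitude envelope: log-power is sinusoidal, matching
        # the lognormal character of cortical band-power fluctuations
        env <- rep(1, n)
        for (i in seq_len(nrow(events))) {
          on <- events$onset[i]
          a <- max(1L, on - spacing_smp %/% 2L)
          bnd <- min(n, on + spacing_smp %/% 2L - 1L)
          t_rel <- (a:bnd - on) / fs
          env[a:bnd] <- exp(0.4 * sin(2 * pi * t_rel / 4 + phi))
        }
        for (ch in which(group == g)) {
          innov <- env * stats::rnorm(n)
          x <- as.numeric(stats::filter(innov, c(a1, a2), method = "recursive"))
          sig[, ch] <- sig[, ch] + bm$amplitude[b] * x / stats::sd(x)
        }
        truth_rows <- rbind(truth_rows, data.frame(
          channel = NA_integer_, group = g, band = bm$band[b],
          crossover = NA_real_, stringsAsFactors = FALSE))
      }
    }
  }

  coupling <- config$coupling
  if (!is.null(coupling)) {
    lo <- coupling$band[1]; hi <- coupling$band[2]
    lag <- as.integer(coupling$lag)
    # Band-limit the driver with a causal AR(2) resonator so the driven
    # group receives only past values of the driver (a zero-phase filter
    # here would leak the driver's future and destroy the direction).
    resonate <- function(x) {
      f0 <- (lo + hi) / 2
      r <- exp(-pi * (hi - lo) / fs)
      y <- as.numeric(stats::filter(x, c(2 * r * cos(2 * pi * f0 / fs), -r^2),
                                    method = "recursive"))
      y / stats::sd(y)
    }
    drvA <- resonate(rowMeans(sig[, group == "NetA", drop = FALSE]))
    drvB <- resonate(rowMeans(sig[, group == "NetB", drop = FALSE]))
    lagged <- function(x, l) c(rep(0, l), x[seq_len(length(x) - l)])
    add_seg <- function(target_grp, drv, a, b) {
      idx <- which(group == target_grp)
      seg <- a:b
      src <- lagged(drv, lag)[seg]
      for (ch in idx) sig[seg, ch] <<- sig[seg, ch] + coupling$strength * src
    }
    for (i in seq_len(nrow(events))) {
      on <- events$onset[i]
      a <- max(1L, on + as.integer(span[1] * fs))
      b <- min(n, on + as.integer(span[2] * fs) - 1L)
      if (isTRUE(coupling$reversal)) {
        add_seg("NetB", drvA, a, on - 1L)       # A drives B before switch
        add_seg("NetA", drvB, on, b)            # B drives A after switch
      } else if (identical(coupling$direction, "A->B")) {
        add_seg("NetB", drvA, a, b)
      } else if (identical(coupling$direction, "B->A")) {
        add_seg("NetA", drvB, a, b)
      } else stop("coupling needs `direction` or `reversal = TRUE`")
    }
  }

  # Contact-level layout: per group one shank with m+1 contacts; the
  # shallowest contact is a shared reference, deeper contacts accumulate
  # the planted channel signals so adjacent differences recover them.
  contacts <- NULL
  contact_sig <- matrix(0, n, k + 2L)
  centroids <- list(NetA = c(-6, -52, 26), NetB = c(26, -62, 52))
  for (g in c("NetA", "NetB")) {
    idx <- which(group == g) # deepest first within the group
    ref <- 0.3 * pink_noise(n, fs, 1)
    # contact at depth d carries ref + sum of channel signals d..m
    depth_sig <- vector("list", length(idx) + 1L)
    depth_sig[[length(idx) + 1L]] <- ref
    for (d in length(idx):1) depth_sig[[d]] <- depth_sig[[d + 1L]] + sig[, idx[d]]
    shank_name <- if (g == "NetA") "A" else "B"
    cen <- centroids[[g]]
    offset <- if (g == "NetA") 0L else length(which(group == "NetA")) + 1L
    for (d in seq_len(length(idx) + 1L)) {
      contact_sig[, offset + d] <- depth_sig[[d]]
      contacts <- rbind(contacts, data.frame(
        name = sprintf("%s%d", shank_name, d), shank = shank_name,
        pos = d,
        x = cen[1] + 1.5 * (d - 1), y = cen[2], z = cen[3],
        broken = FALSE, stringsAsFactors = FALSE))
    }
  }

  rec <- ieeg_recording(contact_sig, fs, contacts, events)
  truth <- list(crossovers = truth_rows, artifacts = NULL,
                group_of_channel = group)

  if (config$artifact_rate > 0) {
    inj <- inject_artifacts(rec, config$artifact_rate,
                            config$artifact_amplitude,
                            duration_s = config$artifact_duration_s,
                            seed = subject_seed(config$seed, s) + 1L)
    rec <- inj$recording
    truth$artifacts <- inj$log
  }
  list(recording = rec, truth = truth)
}

#' Inject transient high-amplitude artifacts
#'
#' Adds rectangular transient deflections of the stated amplitude (in
#' per-channel SD multiples, SD measured before injection) at random
#' onsets following a Poisson process, and returns the artifact log.
#'
#' @param recording an [ieeg_recording].
#' @param rate events per minute (0 returns the input unchanged).
#' @param amplitude_sd deflection amplitude in channel-SD multiples.
#' @param duration_s event duration in seconds.
#' @param seed RNG seed for onset/channel placement.
#' @return list with `recording` (artifacts added) and `log`
#'   (data frame: onset sample, duration_s, channel).
#' @export
inject_artifacts <- function(recording, rate, amplitude_sd,
                             duration_s = 0.05, seed = 1) {
  stopifnot(inherits(recording, "ieeg_recording"))
  if (rate <= 0)
    return(list(recording = recording,
                log = data.frame(onset = integer(0), duration_s = numeric(0),
                                 channel = integer(0))))
  set.seed(seed)
  n <- nrow(recording$signal)
  k <- ncol(recording$signal)
  fs <- recording$fs
  minutes <- n / fs / 60
  n_ev <- stats::rpois(1, rate * minutes)
  dur <- as.integer(round(duration_s * fs))
  log <- data.frame(onset = integer(0), duration_s = numeric(0),
                    channel = integer(0))
  if (n_ev > 0) {
    sds <- apply(recording$signal, 2, stats::sd)
    onsets <- sort(sample.int(n - dur - 1L, n_ev, replace = FALSE))
    chans <- sample.int(k, n_ev, replace = TRUE)
    signs <- sample(c(-1, 1), n_ev, replace = TRUE)
    for (i in seq_len(n_ev)) {
      seg <- onsets[i]:(onsets[i] + dur - 1L)
      recording$signal[seg, chans[i]] <-
        recording$signal[seg, chans[i]] + signs[i] * amplitude_sd * sds[chans[i]]
    }
    log <- data.frame(onset = onsets, duration_s = dur / fs, channel = chans)
  }
  list(recording = recording, log = log)
}
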