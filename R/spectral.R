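# Time-resolved band power: STFT (band-dependent Hann windows) and Morlet
# wavelet estimators, dB transform, session-wide z-score normalization and
# band averaging into the six analysis bands.

# Window length (s) used for each analysis band: the delta band uses a 2 s
# window, theta 1 s, all faster bands 0.5 s.
window_for_band <- function(band) {
  switch(band, delta = 2, theta = 1, 0.5)
}

# Band-power time step: 31.25 ms (16 samples at 512 Hz).
RBP_STEP_S <- 0.03125

#' Sliding-window Hann-weighted power spectral density
#'
#' Slides a Hann-weighted window over the signal in steps of
#' `step_s` (default 31.25 ms) and computes the periodogram at each step.
#' Window centers fall on the shared step grid (sample indices
#' `1 + k * step`), so tensors from different window lengths align in
#' time. Power is converted to dB with a relative floor
#' (`10*log10(power + 1e-12 * median(power))`) so silent inputs stay
#' finite.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds.
#' @param step_s time step in seconds (default 0.03125).
#' @param fsel optional frequency range `c(lo, hi)` (Hz) to retain.
#' @return object of class `psd_tensor`: list with `db` (time x freq x
#'   channel array, dB), `freqs` (Hz), `centers` (window-center sample
#'   indices), `step` (samples), `fs`.
#' @export
stft_psd <- function(x, fs, window_s, step_s = RBP_STEP_S, fsel = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x); k <- ncol(x)
  L <- as.integer(round(window_s * fs))
  step <- as.integer(round(step_s * fs))
  if (n < L) stop("signal shorter than the analysis window")
  half <- L %/% 2L
  kmin <- as.integer(ceiling(half / step))
  kmax <- (n - half - (L - 2L * half)) %/% step # ensure start+L-1 <= n
  while (1L + kmax * step - half + L - 1L > n) kmax <- kmax - 1L
  if (kmax < kmin) stop("signal shorter than the analysis window")
  ks <- kmin:kmax
  centers <- 1L + ks * step
  starts <- centers - half
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1)) # Hann
  scale <- 2 / (fs * sum(w^2))
  freqs <- (0:(L %/% 2)) * fs / L
  fkeep <- rep(TRUE, length(freqs))
  if (!is.null(fsel)) fkeep <- freqs >= fsel[1] & freqs <= fsel[2]
  nf <- sum(fkeep)
  nw <- length(starts)
  fk_idx <- which(fkeep)
  out <- array(NA_real_, c(nw, nf, k))
  chunk <- max(1L, as.integer(2^22 / L))
  for (ch in seq_len(k)) {
    pw <- matrix(NA_real_, nf, nw) # freq x window; transposed once below
    xc <- x[, ch]
    i <- 1L
    while (i <= nw) {
      j <- min(nw, i + chunk - 1L)
      idx <- outer(0:(L - 1L), starts[i:j], "+")
      seg <- xc[idx]
      dim(seg) <- dim(idx)
      X <- stats::mvfft(seg * w)[fk_idx, , drop = FALSE]
      p <- (Re(X)^2 + Im(X)^2) * scale
      if (fk_idx[1] == 1L) p[1, ] <- p[1, ] / 2 # DC bin is not doubled
      pw[, i:j] <- p
      i <- j + 1L
    }
    out[, , ch] <- db_power(t(pw))
  }
  structure(list(db = out, freqs = freqs[fkeep], centers = centers,
                 step = step, fs = fs),
            class = "psd_tensor")
}

# dB with a per-input relative power floor (1e-12 of the median power).
db_power <- function(p) {
  floor_p <- 1e-12 * stats::median(p)
  if (!is.finite(floor_p) || floor_p <= 0) floor_p <- 1e-300
  10 * log10(p + floor_p)
}

#' Session-wide z-score normalization factors
#'
#' Mean and SD of the dB PSD per frequency bin and channel, computed
#' across all window positions of the recording session (task periods
#' included). These factors compensate the 1/f power decay.
#'
#' @param psd a `psd_tensor` from [stft_psd()] or [wavelet_psd()].
#' @return list with `mu` and `sigma` (freq x channel matrices).
#' @export
norm_factors <- function(psd) {
  nf <- length(psd$freqs); k <- dim(psd$db)[3]
  mu <- matrix(NA_real_, nf, k); sg <- matrix(NA_real_, nf, k)
  for (ch in seq_len(k)) {
    mu[, ch] <- colMeans(psd$db[, , ch, drop = FALSE][, , 1])
    sg[, ch] <- apply(psd$db[, , ch, drop = FALSE][, , 1], 2, stats::sd)
  }
  list(mu = mu, sigma = sg)
}

#' z-score a PSD tensor
#'
#' `PSD_norm = (PSD - mu) / sigma` per frequency bin and channel.
#' Bins with zero SD are dropped with a warning.
#'
#' @param psd a `psd_tensor` (dB).
#' @param factors normalization factors from [norm_factors()]; defaults
#'   to factors computed from `psd` itself.
#' @return normalized `psd_tensor` (z-score units).
#' @export
normalize_psd <- function(psd, factors = norm_factors(psd)) {
  keep <- apply(factors$sigma > 0, 1, all)
  if (any(!keep)) {
    warning(sprintf("%d zero-variance frequency bin(s) dropped", sum(!keep)))
    psd$db <- psd$db[, keep, , drop = FALSE]
    psd$freqs <- psd$freqs[keep]
    factors$mu <- factors$mu[keep, , drop = FALSE]
    factors$sigma <- factors$sigma[keep, , drop = FALSE]
  }
  for (ch in seq_len(dim(psd$db)[3]))
    psd$db[, , ch] <- sweep(sweep(psd$db[, , ch, drop = FALSE][, , 1], 2,
                                  factors$mu[, ch]), 2,
                            factors$sigma[, ch], "/")
  psd$normalized <- TRUE
  psd
}

# Frequency bins belonging to a band, excluding the notched line-noise
# ranges from the high-gamma band.
band_bins <- function(freqs, band, lo, hi) {
  sel <- freqs >= lo & freqs <= hi
  if (band == "hgb")
    for (nr in notch_ranges()) sel <- sel & !(freqs > nr[1] & freqs < nr[2])
  sel
}

#' Average normalized PSD bins into frequency bands
#'
#' Arithmetic mean of z-scored bins within each requested band. Bins in
#' the notched ranges (48-52, 98-102 Hz) are never included in the
#' high-gamma band.
#'
#' @param psd a normalized `psd_tensor`.
#' @param bands data frame as [analysis_bands()] (possibly a subset).
#' @return array time x band x channel with band names on dimnames.
#' @export
band_average <- function(psd, bands = analysis_bands()) {
  nw <- dim(psd$db)[1]; k <- dim(psd$db)[3]
  out <- array(NA_real_, c(nw, nrow(bands), k),
               dimnames = list(NULL, bands$band, NULL))
  for (b in seq_len(nrow(bands))) {
    sel <- band_bins(psd$freqs, bands$band[b], bands$lo[b], bands$hi[b])
    if (!any(sel))
      stop(sprintf("no frequency bins available for band %s", bands$band[b]))
    for (ch in seq_len(k))
      out[, b, ch] <- rowMeans(psd$db[, sel, ch, drop = FALSE])
  }
  out
}

#' Morlet wavelet power spectral density
#'
#' Constant-Q complex Morlet wavelets (default 6 cycles) applied in the
#' frequency domain; power is sampled at the same window-center grid as
#' the STFT path and converted to dB with the same floor.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param fs sampling rate (Hz).
#' @param freqs center frequencies (Hz).
#' @param n_cycles wavelet width in cycles (default 6).
#' @param step_s time step (s) of the output grid.
#' @return a `psd_tensor` (dB).
#' @export
wavelet_psd <- function(x, fs, freqs, n_cycles = 6, step_s = RBP_STEP_S) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x); k <- ncol(x)
  step <- as.integer(round(step_s * fs))
  ks <- 1:((n - 1L) %/% step)
  centers <- 1L + ks * step
  # FFT length divisible by the output step so the analytic signal can be
  # evaluated directly on the decimated grid: decimation in time equals
  # aliasing (folding) in frequency, replacing a full-length inverse FFT
  # per frequency by one of length nfft/step.
  nfft <- step * stats::nextn(ceiling(2^ceiling(log2(n)) / step), c(2, 3, 5))
  m_dec <- nfft %/% step
  fgrid <- fft_freqs(nfft, fs)
  nw <- length(centers); nf <- length(freqs)
  out <- array(NA_real_, c(nw, nf, k))
  for (ch in seq_len(k)) {
    X <- stats::fft(c(x[, ch], rep(0, nfft - n)))
    pw <- matrix(NA_real_, nw, nf)
    for (fi in seq_len(nf)) {
      f0 <- freqs[fi]
      sigma_f <- f0 / n_cycles
      G <- 2 * exp(-(fgrid - f0)^2 / (2 * sigma_f^2))
      G[fgrid < 0] <- 0
      Yf <- X * G
      dim(Yf) <- c(m_dec, step)
      folded <- rowSums(Yf)
      xa <- stats::fft(folded, inverse = TRUE) / nfft
      # xa[j] is the analytic signal at sample 1 + (j-1)*step
      pw[, fi] <- (Re(xa[ks + 1L])^2 + Im(xa[ks + 1L])^2)
    }
    out[, , ch] <- db_power(pw)
  }
  structure(list(db = out, freqs = freqs, centers = centers,
                 step = step, fs = fs),
            class = "psd_tensor")
}

# STFT frequency grids per window group, restricted to what each band
# needs (keeps memory bounded on long sessions).
group_plan <- function(bands) {
  groups <- list()
  for (b in seq_len(nrow(bands))) {
    wl <- window_for_band(bands$band[b])
    key <- as.character(wl)
    if (is.null(groups[[key]]))
      groups[[key]] <- list(window_s = wl, bands = bands[b, , drop = FALSE])
    else groups[[key]]$bands <- rbind(groups[[key]]$bands, bands[b, ])
  }
  groups
}

#' Session-level relative band power
#'
#' Runs the full band-power chain on a continuous recording: sliding
#' spectral estimation with the band-appropriate window (2 s for delta,
#' 1 s for theta, 0.5 s otherwise), dB transform, session-wide z-score
#' per frequency bin and channel, and band averaging. The wavelet
#' estimator shares the z-scoring and band averaging and is evaluated on
#' the same time grid.
#'
#' @param recording an [ieeg_recording] (bipolar channels).
#' @param bands band definition data frame (default [analysis_bands()]).
#' @param estimator `"stft"` or `"wavelet"`.
#' @param step_s band-power time step (default 31.25 ms).
#' @return object of class `rbp_session`: list with `rbp` (time x band x
#'   channel array, z-score units), `centers` (sample indices), `step`
#'   (samples), `fs`, `bands`, `channels`, `events`.
#' @export
session_rbp <- function(recording, bands = analysis_bands(),
                        estimator = c("stft", "wavelet"),
                        step_s = RBP_STEP_S) {
  stopifnot(inherits(recording, "ieeg_recording"))
  estimator <- match.arg(estimator)
  fs <- recording$fs
  x <- recording$signal
  k <- ncol(x)
  groups <- group_plan(bands)
  pieces <- list()
  for (g in groups) {
    gb <- g$bands
    frange <- c(max(0.05, min(gb$lo) - 0.01), max(gb$hi) + 0.01)
    centers <- NULL
    rbp_g <- NULL
    for (ch in seq_len(k)) { # per channel to bound memory
      if (estimator == "stft") {
        psd <- stft_psd(x[, ch], fs, g$window_s, step_s, fsel = frange)
      } else {
        L <- as.integer(round(g$window_s * fs))
        df <- fs / L
        fg <- seq(df, fs / 2, by = df)
        fg <- fg[fg >= frange[1] & fg <= frange[2]]
        psd <- wavelet_psd(x[, ch], fs, fg, step_s = step_s)
      }
      psd <- normalize_psd(psd)
      ba <- band_average(psd, gb)
      if (is.null(rbp_g)) {
        centers <- psd$centers
        rbp_g <- array(NA_real_, c(dim(ba)[1], dim(ba)[2], k),
                       dimnames = list(NULL, gb$band, NULL))
      }
      rbp_g[, , ch] <- ba[, , 1]
    }
    pieces[[length(pieces) + 1L]] <-
      list(centers = centers, rbp = rbp_g, bands = gb$band)
  }
  common <- Reduce(intersect, lapply(pieces, `[[`, "centers"))
  rbp <- array(NA_real_, c(length(common), nrow(bands), k),
               dimnames = list(NULL, bands$band, NULL))
  for (p in pieces) {
    sel <- match(common, p$centers)
    rbp[, p$bands, ] <- p$rbp[sel, , , drop = FALSE]
  }
  structure(list(rbp = rbp, centers = common,
                 step = as.integer(round(step_s * fs)), fs = fs,
                 bands = bands$band, channels = recording$contacts,
                 events = recording$events),
            class = "rbp_session")
}

#' Epoch session band power into trials
#'
#' Cuts the session-level band-power time courses into trials around each
#' event, on the shared 31.25 ms grid, with t = 0 at the event onset.
#'
#' @param rbp an `rbp_session` from [session_rbp()].
#' @param crop trial window in seconds (default the analysis crop
#'   `c(-2.3, 2.3)`).
#' @param max_per_condition cap on trials per condition (default 60).
#' @return object of class `rbp_tensor`: list with `rbp` (time x band x
#'   channel x trial), `time` (s), `bands`, `condition` (per trial),
#'   `channels`, `step_s`.
#' @export
epoch_rbp <- function(rbp, crop = c(-2.3, 2.3), max_per_condition = 60) {
  stopifnot(inherits(rbp, "rbp_session"))
  ev <- rbp$events
  step <- rbp$step
  n_pre <- as.integer(floor(-crop[1] / (step / rbp$fs)))
  n_post <- as.integer(floor(crop[2] / (step / rbp$fs)))
  rel <- (-n_pre):n_post
  kmin <- min(rbp$centers)
  ok <- logical(nrow(ev))
  pos0 <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    k0 <- as.integer(round((ev$onset[i] - 1) / step))
    pos0[i] <- k0
    cmin <- 1L + (k0 - n_pre) * step
    cmax <- 1L + (k0 + n_post) * step
    ok[i] <- cmin >= min(rbp$centers) && cmax <= max(rbp$centers)
  }
  if (any(!ok))
    warning(sprintf("%d trial(s) outside the band-power grid; dropped",
                    sum(!ok)))
  ev <- ev[ok, , drop = FALSE]; pos0 <- pos0[ok]
  sel <- unlist(lapply(split(seq_len(nrow(ev)), ev$condition),
                       utils::head, max_per_condition))
  sel <- sort(sel)
  ev <- ev[sel, , drop = FALSE]; pos0 <- pos0[sel]
  k_grid0 <- as.integer(round((kmin - 1) / step)) # first center's step index
  nt <- length(rel); nb <- dim(rbp$rbp)[2]; k <- dim(rbp$rbp)[3]
  out <- array(NA_real_, c(nt, nb, k, nrow(ev)),
               dimnames = list(NULL, rbp$bands, NULL, NULL))
  for (i in seq_len(nrow(ev))) {
    rows <- pos0[i] + rel - k_grid0 + 1L
    out[, , , i] <- rbp$rbp[rows, , , drop = FALSE]
  }
  structure(list(rbp = out, time = rel * step / rbp$fs, bands = rbp$bands,
                 condition = ev$condition, channels = rbp$channels,
                 step_s = step / rbp$fs),
            class = "rbp_tensor")
}

#' Condition-mean band power
#'
#' @param rbp an `rbp_tensor`.
#' @return array time x band x channel x condition (conditions
#'   `ext2int`, `int2ext` on the last dimension).
#' @export
condition_means <- function(rbp) {
  stopifnot(inherits(rbp, "rbp_tensor"))
  conds <- c("ext2int", "int2ext")
  d <- dim(rbp$rbp)
  out <- array(NA_real_, c(d[1], d[2], d[3], 2),
               dimnames = list(NULL, rbp$bands, NULL, conds))
  for (ci in 1:2) {
    sel <- rbp$condition == conds[ci]
    out[, , , ci] <- apply(rbp$rbp[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  }
  out
}
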