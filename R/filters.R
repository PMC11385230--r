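#' @keywords internal
"_PACKAGE"

# Frequency bands used throughout the band-power analysis (Hz).
# The high-gamma band excludes the notched ranges 48-52 and 98-102 Hz.

#' Analysis frequency bands
#'
#' The six non-overlapping frequency bands into which normalized spectra are
#' averaged: delta (0.1-3 Hz), theta (4-7 Hz), alpha (8-12 Hz),
#' beta (13-30 Hz), low-gamma (31-48 Hz) and high-gamma (HGB, 52-120 Hz).
#' Spectral bins falling inside the notched ranges (48-52 and 98-102 Hz)
#' are never averaged into the HGB.
#'
#' @return A data frame with columns `band`, `lo`, `hi` (Hz).
#' @export
analysis_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "lgamma", "hgb"),
    lo   = c(0.1, 4, 8, 13, 31, 52),
    hi   = c(3, 7, 12, 30, 48, 120),
    stringsAsFactors = FALSE
  )
}

# Notched-out line-noise ranges (Hz); open intervals when excluding bins.
notch_ranges <- function() list(c(48, 52), c(98, 102))

#' Butterworth magnitude-squared gain
#'
#' Amplitude gain of a forward-backward (zero-phase) Butterworth filter of
#' the given order, evaluated at frequencies `f`. Forward-backward
#' application squares the magnitude response, so the applied gain is
#' `1 / (1 + (f/fc)^(2n))` for a low-pass of order `n`, and the standard
#' band transformations for the other types.
#'
#' @param f numeric vector of frequencies (Hz, non-negative).
#' @param type one of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @param edges cutoff (length 1) or band edges (length 2), Hz.
#' @param order filter order `n`.
#' @return numeric vector of gains in `[0, 1]`.
#' @export
butter_gain <- function(f, type = c("low", "high", "pass", "stop"),
                        edges, order = 6) {
  type <- match.arg(type)
  f <- abs(f)
  eps <- .Machine$double.xmin
  if (type %in% c("pass", "stop") && length(edges) != 2)
    stop("band filters need two edge frequencies")
  g <- switch(type,
    low  = 1 / (1 + (f / edges[1])^(2 * order)),
    high = 1 / (1 + (edges[1] / pmax(f, eps))^(2 * order)),
    pass = {
      f0sq <- edges[1] * edges[2]
      bw <- edges[2] - edges[1]
      x <- (f^2 - f0sq) / pmax(f * bw, eps)
      1 / (1 + x^(2 * order))
    },
    stop = {
      f0sq <- edges[1] * edges[2]
      bw <- edges[2] - edges[1]
      x <- (f * bw) / pmax(abs(f^2 - f0sq), eps)
      g <- 1 / (1 + x^(2 * order))
      g[f >= edges[1] & f <= edges[2] & abs(f^2 - f0sq) < 1e-9] <- 0
      g
    })
  # squared for zero-phase (forward-backward) application
  g^2
}

# FFT frequencies (Hz) for length n at sampling rate fs, fft() bin order.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Zero-phase Butterworth filtering
#'
#' Applies a zero-phase Butterworth filter spectrally: the signal is
#' reflect-padded, transformed with the FFT, multiplied by the
#' forward-backward Butterworth magnitude response and transformed back.
#' This matches the steady-state response of `filtfilt`-style
#' forward-backward filtering while remaining numerically stable for
#' very low relative cutoffs (e.g. a 0.1 Hz high-pass at 512 Hz).
#'
#' Cascaded filters combine exactly in the frequency domain, so a list of
#' filter specifications is applied in a single transform round.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param fs sampling rate (Hz).
#' @param type filter type, see [butter_gain()], or a list of
#'   `list(type, edges, order)` specs applied as a cascade (then `edges`
#'   and `order` are ignored).
#' @param edges cutoff/edge frequencies (Hz).
#' @param order Butterworth order (default 6).
#' @return filtered signal, same shape as `x`.
#' @export
zerophase_filter <- function(x, fs, type, edges = NULL, order = 6) {
  specs <- if (is.list(type)) type
           else list(list(type = type, edges = edges, order = order))
  for (sp in specs)
    if (any(sp$edges >= fs / 2) && sp$type != "high")
      stop(sprintf("filter band [%s] Hz exceeds Nyquist (%.1f Hz)",
                   paste(sp$edges, collapse = ", "), fs / 2))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  # The DC pedestal is handled analytically (gain at f = 0) so that it
  # cannot leak through the finite-length transform; the remaining signal
  # is reflect-padded to suppress edge transients.
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  g0 <- prod(vapply(specs, function(sp)
    butter_gain(0, sp$type, sp$edges, sp$order), numeric(1)))
  npad <- min(n - 1L, as.integer(round(2 * fs)))
  idx_pre <- if (npad > 0) (npad + 1L):2L else integer(0)
  idx_post <- if (npad > 0) (n - 1L):(n - npad) else integer(0)
  xp <- rbind(x[idx_pre, , drop = FALSE], x, x[idx_post, , drop = FALSE])
  np <- nrow(xp)
  nfft <- stats::nextn(np, c(2, 3, 5))
  if (nfft > np) xp <- rbind(xp, matrix(0, nfft - np, ncol(xp)))
  fgrid <- fft_freqs(nfft, fs)
  g <- rep(1, nfft)
  for (sp in specs) g <- g * butter_gain(fgrid, sp$type, sp$edges, sp$order)
  y <- Re(stats::mvfft(stats::mvfft(xp) * g, inverse = TRUE)) / nfft
  y <- y[(npad + 1L):(npad + n), , drop = FALSE]
  y <- sweep(y, 2, mu * g0, "+")
  if (vec) drop(y) else y
}

#' Analytic signal via the Hilbert transform
#'
#' @param x numeric vector or matrix (samples x channels).
#' @return complex analytic signal, same shape as `x`.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  y <- stats::mvfft(X * h, inverse = TRUE) / n
  if (vec) drop(y) else y
}

# Logistic transition from -0.5 to +0.5 centered at 0; `width` is the
# 12%-88% transition width in the same units as t.
logistic_step <- function(t, width) 1 / (1 + exp(-4 * t / width)) - 0.5
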