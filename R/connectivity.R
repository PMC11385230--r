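# Time-resolved directed connectivity from sliding-window MVAR models
# (DTF, PDC, Granger-Geweke causality) and non-directed phase-locking
# value from narrow-band Hilbert phases.

#' MVAR fitting bands
#'
#' The four frequency bands in which sliding-window MVAR models are fit
#' (0.1-30, 31-48, 52-98, 102-120 Hz, leaving out the 50 Hz line and its
#' harmonic), with the default model order equal to the integer
#' bandwidth in Hz.
#'
#' @return data frame with columns `lo`, `hi` (Hz) and `order`.
#' @export
mvar_fit_bands <- function() {
  data.frame(lo = c(0.1, 31, 52, 102), hi = c(30, 48, 98, 120),
             order = c(29L, 17L, 46L, 18L))
}

#' Temporal z-scoring and band-splitting of trials
#'
#' z-scores each trial of each channel in the temporal domain, then
#' band-pass filters (zero-phase 6th-order Butterworth; low-pass for the
#' lowest band) into the four MVAR fitting bands 0.1-30, 31-48, 52-98 and
#' 102-120 Hz.
#'
#' @param trials a `trial_tensor` (see [extract_trials()]).
#' @param bands data frame with `lo`, `hi` (default [mvar_fit_bands()]).
#' @return list of `trial_tensor`s, one per band, each with a `band`
#'   element.
#' @export
band_split <- function(trials, bands = mvar_fit_bands()) {
  stopifnot(inherits(trials, "trial_tensor"))
  d <- dim(trials$data)
  z <- trials$data
  for (ch in seq_len(d[2])) for (tr in seq_len(d[3])) {
    v <- z[, ch, tr]
    s <- stats::sd(v)
    z[, ch, tr] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  }
  out <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    lo <- bands$lo[b]; hi <- bands$hi[b]
    bt <- trials
    x <- matrix(z, nrow = d[1]) # time x (ch*trial)
    y <- if (lo <= 0.5) zerophase_filter(x, trials$fs, "low", hi)
         else zerophase_filter(x, trials$fs, "pass", c(lo, hi))
    bt$data <- array(y, d)
    bt$band <- c(lo, hi)
    bt$order <- if (!is.null(bands$order)) bands$order[b] else NA_integer_
    out[[b]] <- bt
  }
  out
}

#' Fit a multivariate autoregressive model in a time window
#'
#' Ordinary least-squares fit of `X(t) = sum_l A(l) X(t-l) + E(t)`,
#' pooling all supplied trials as independent realizations: lagged
#' predictors never cross trial boundaries, and only samples whose full
#' lag history lies inside the window contribute rows. The residual
#' covariance `Z` is estimated from the pooled residuals.
#'
#' @param data numeric array time x channels x trials (a window slice).
#' @param p model order (number of lags), `p >= 1`.
#' @param fs sampling rate (Hz).
#' @return object of class `mvar_model`: list with `A` (k x k x p; `A[m,n,l]`
#'   is the influence of channel n at lag l on channel m), `Z` (k x k
#'   residual covariance), `p`, `fs`, `nobs`.
#' @export
fit_mvar <- function(data, p, fs) {
  stopifnot(length(dim(data)) == 3)
  if (p < 1) stop("model order p must be at least 1")
  d <- dim(data)
  S <- d[1]; k <- d[2]; ntr <- d[3]
  if (S <= p) stop("window shorter than the model order")
  rows_per_trial <- S - p
  nobs <- rows_per_trial * ntr
  if (nobs < 10 * k * p)
    warning(sprintf(
      "only %d observations for %d parameters per equation; fit may be noisy",
      nobs, k * p))
  Y <- matrix(aperm(data[(p + 1):S, , , drop = FALSE], c(1, 3, 2)),
              nrow = nobs, ncol = k)
  X <- matrix(NA_real_, nobs, k * p)
  for (l in seq_len(p)) {
    Xl <- matrix(aperm(data[(p + 1 - l):(S - l), , , drop = FALSE],
                       c(1, 3, 2)), nrow = nobs, ncol = k)
    X[, (l - 1) * k + seq_len(k)] <- Xl
  }
  XtX <- crossprod(X)
  # Band-limited signals make the design ill-conditioned; stabilize the
  # normal equations with a tiny relative ridge before falling back.
  scale_d <- mean(diag(XtX))
  ch <- NULL
  for (lambda in c(0, 1e-10, 1e-8, 1e-6) * scale_d) {
    ch <- tryCatch(chol(XtX + diag(lambda, ncol(XtX))),
                   error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch))
    stop("rank-deficient MVAR design; lower the order p or use fewer channels")
  B <- backsolve(ch, forwardsolve(t(ch), crossprod(X, Y)))
  resid <- Y - X %*% B
  Z <- crossprod(resid) / (nobs - k * p)
  A <- array(0, c(k, k, p))
  for (l in seq_len(p)) A[, , l] <- t(B[(l - 1) * k + seq_len(k), , drop = FALSE])
  structure(list(A = A, Z = Z, p = p, fs = fs, nobs = nobs),
            class = "mvar_model")
}

# Fourier-transformed coefficient matrix Abar(f) = I - sum_l A(l) e^{-i2pi f l/fs}
mvar_abar <- function(model, f) {
  k <- dim(model$A)[1]
  Ab <- diag(k) + 0i
  for (l in seq_len(model$p))
    Ab <- Ab - model$A[, , l] * exp(-2i * pi * f * l / model$fs)
  Ab
}

#' MVAR transfer function
#'
#' `H(f) = (I - sum_l A(l) exp(-i 2 pi f l / fs))^{-1}` evaluated at the
#' requested frequencies.
#'
#' @param model an `mvar_model`.
#' @param freqs frequencies (Hz).
#' @return complex array k x k x length(freqs).
#' @export
transfer_function <- function(model, freqs) {
  k <- dim(model$A)[1]
  H <- array(NA_complex_, c(k, k, length(freqs)))
  for (i in seq_along(freqs)) {
    Ab <- mvar_abar(model, freqs[i])
    Hi <- tryCatch(solve(Ab), error = function(e) NULL)
    if (is.null(Hi))
      stop(sprintf("singular coefficient matrix at %g Hz", freqs[i]))
    H[, , i] <- Hi
  }
  H
}

#' Directed transfer function
#'
#' `DTF[m,n](f) = |H[m,n](f)| / sqrt(sum_j |H[m,j](f)|^2)`: the inflow
#' from channel n to channel m normalized by the total inflow to m.
#' Row sums of squares equal 1 at every frequency.
#'
#' @param H transfer-function array from [transfer_function()].
#' @return array k x k x nf in `[0, 1]`.
#' @export
dtf <- function(H) {
  d <- dim(H)
  out <- array(NA_real_, d)
  for (i in seq_len(d[3])) {
    M <- Mod(H[, , i])
    denom <- sqrt(rowSums(M^2))
    if (any(denom == 0)) stop("zero row in transfer function")
    out[, , i] <- M / denom
  }
  out
}

#' Partial directed coherence
#'
#' `PDC[m,n](f) = |Abar[m,n](f)| / sqrt(Abar_n*(f) Abar_n(f))` with
#' `Abar(f) = I - sum_l A(l) exp(-i 2 pi f l / fs)`: the outflow from
#' channel n to channel m normalized by the total outflow of n.
#' Column sums of squares equal 1 at every frequency.
#'
#' @param model an `mvar_model`.
#' @param freqs frequencies (Hz).
#' @return array k x k x nf in `[0, 1]`.
#' @export
pdc <- function(model, freqs) {
  k <- dim(model$A)[1]
  out <- array(NA_real_, c(k, k, length(freqs)))
  for (i in seq_along(freqs)) {
    Ab <- mvar_abar(model, freqs[i])
    M <- Mod(Ab)
    denom <- sqrt(colSums(M^2))
    if (any(denom == 0)) stop("zero column in coefficient matrix")
    out[, , i] <- sweep(M, 2, denom, "/")
  }
  out
}

#' Granger-Geweke causality
#'
#' `GGC[m,n](f) = (Z[n,n] - Z[m,n]^2 / Z[m,m]) |H[m,n](f)|^2 / |S[m,m](f)|`
#' with the model spectrum `S(f) = H(f) Z H*(f)`; computed from the full
#' multivariate model (not pairwise refits). Non-negative everywhere.
#'
#' @param model an `mvar_model`.
#' @param H transfer-function array (from [transfer_function()]).
#' @param freqs frequencies (Hz) matching `H`.
#' @return array k x k x nf, `GGC >= 0`.
#' @export
ggc <- function(model, H, freqs) {
  Z <- model$Z
  ev <- eigen(Z, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("residual covariance is not positive definite")
  k <- dim(H)[1]
  out <- array(NA_real_, c(k, k, length(freqs)))
  for (i in seq_along(freqs)) {
    Hi <- H[, , i]
    S <- Hi %*% Z %*% Conj(t(Hi))
    Smm <- Mod(diag(S))
    for (m in seq_len(k)) for (n in seq_len(k)) {
      num <- (Z[n, n] - Z[m, n]^2 / Z[m, m]) * Mod(Hi[m, n])^2
      out[m, n, i] <- num / Smm[m]
    }
  }
  out
}

#' Model-implied spectrum
#'
#' Diagonal of `S(f) = H(f) Z H*(f)`: the band power each channel's MVAR
#' model accounts for, used to check spectral fidelity against the STFT
#' band power.
#'
#' @param model an `mvar_model`.
#' @param freqs frequencies (Hz).
#' @return matrix channels x frequencies (linear power).
#' @export
mvar_spectrum <- function(model, freqs) {
  H <- transfer_function(model, freqs)
  k <- dim(H)[1]
  out <- matrix(NA_real_, k, length(freqs))
  for (i in seq_along(freqs))
    out[, i] <- Mod(diag(H[, , i] %*% model$Z %*% Conj(t(H[, , i]))))
  out
}

# Sliding-window positions: 500 ms windows stepped 125 ms over the crop.
sliding_windows <- function(time, fs, win_s = 0.5, step_s = 0.125,
                            crop = c(-2.3, 2.3)) {
  starts_t <- seq(crop[1], crop[2] - win_s + 1e-9, by = step_s)
  win <- as.integer(round(win_s * fs))
  i0 <- vapply(starts_t, function(t0) which.min(abs(time - t0)), integer(1))
  list(start = i0, len = win, center_t = starts_t + win_s / 2)
}

#' Sliding-window inter-network directed connectivity
#'
#' z-scores trials temporally, band-splits them, fits an MVAR model per
#' condition in each 500 ms window (stepped 125 ms over the analysis
#' crop), evaluates the requested measure on a 1 Hz grid inside each
#' fitting band, z-scores along time per (pair, frequency, condition),
#' averages frequencies into the six analysis bands and finally averages
#' over all directed channel pairs between the two networks.
#'
#' @param trials a `trial_tensor` whose channel table has a `group`
#'   column (or supply `groups`).
#' @param groups named list mapping the two network names to channel
#'   indices.
#' @param measure `"dtf"`, `"pdc"` or `"ggc"`.
#' @param fit_bands data frame of fitting bands and orders
#'   (default [mvar_fit_bands()]; subset to save time when only some
#'   analysis bands are needed).
#' @param win_s,step_s sliding-window length and step (s).
#' @param crop analysis crop (s).
#' @param zscore z-score along the temporal dimension (default TRUE).
#' @return list with `series` (4-D array: time x band x direction x
#'   condition; directions `"A->B"` and `"B->A"` where A is the first
#'   network in `groups`), `center_t`, `bands`, `conditions`,
#'   `directions`.
#' @export
sliding_connectivity <- function(trials, groups,
                                 measure = c("dtf", "pdc", "ggc"),
                                 fit_bands = mvar_fit_bands(),
                                 win_s = 0.5, step_s = 0.125,
                                 crop = c(-2.3, 2.3), zscore = TRUE) {
  measure <- match.arg(measure)
  stopifnot(length(groups) == 2)
  nmA <- names(groups)[1]; nmB <- names(groups)[2]
  chA <- groups[[1]]; chB <- groups[[2]]
  if (length(chA) < 1 || length(chB) < 1)
    stop("each network needs at least one channel")
  keep <- c(chA, chB)
  sub <- trials
  sub$data <- trials$data[, keep, , drop = FALSE]
  iA <- seq_along(chA); iB <- length(chA) + seq_along(chB)
  bands <- analysis_bands()
  split_tr <- band_split(sub, fit_bands)
  conds <- c("ext2int", "int2ext")
  wins <- sliding_windows(trials$time, trials$fs, win_s, step_s, crop)
  nwin <- length(wins$start)
  k <- length(keep)
  # accumulate z-scored frequency-resolved values into analysis bands
  series <- array(0, c(nwin, nrow(bands), 2, 2),
                  dimnames = list(NULL, bands$band, c("A->B", "B->A"), conds))
  counts <- array(0L, c(nrow(bands)))
  band_counts <- matrix(0, nwin, nrow(bands)) # freqs accumulated per band
  nfreq_in_band <- numeric(nrow(bands))
  for (bt in split_tr) {
    lo <- max(1, ceiling(bt$band[1])); hi <- floor(bt$band[2])
    freqs <- seq(lo, hi)
    freqs <- freqs[freqs <= trials$fs / 2 - 1]
    if (!length(freqs)) next
    p <- bt$order
    for (ci in 1:2) {
      sel <- bt$condition == conds[ci]
      vals <- array(NA_real_, c(k, k, length(freqs), nwin))
      for (w in seq_len(nwin)) {
        idx <- wins$start[w]:(wins$start[w] + wins$len - 1L)
        model <- fit_mvar(bt$data[idx, , sel, drop = FALSE], p, trials$fs)
        vals[, , , w] <- switch(measure,
          dtf = dtf(transfer_function(model, freqs)),
          pdc = pdc(model, freqs),
          ggc = {
            H <- transfer_function(model, freqs)
            ggc(model, H, freqs)
          })
      }
      if (zscore) {
        for (m in seq_len(k)) for (n in seq_len(k)) for (fi in seq_along(freqs)) {
          v <- vals[m, n, fi, ]
          s <- stats::sd(v)
          vals[m, n, fi, ] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
        }
      }
      for (b in seq_len(nrow(bands))) {
        fsel <- band_bins(freqs, bands$band[b], bands$lo[b], bands$hi[b])
        if (!any(fsel)) next
        # direction A->B: source in A (n), target in B (m)
        ab <- apply(vals[iB, iA, fsel, , drop = FALSE], 4, mean)
        ba <- apply(vals[iA, iB, fsel, , drop = FALSE], 4, mean)
        wgt <- sum(fsel)
        series[, b, 1, ci] <- series[, b, 1, ci] + ab * wgt
        series[, b, 2, ci] <- series[, b, 2, ci] + ba * wgt
        if (ci == 1) nfreq_in_band[b] <- nfreq_in_band[b] + wgt
      }
    }
  }
  for (b in seq_len(nrow(bands))) {
    if (nfreq_in_band[b] == 0) series[, b, , ] <- NA_real_
    else series[, b, , ] <- series[, b, , ] / nfreq_in_band[b]
  }
  list(series = series, center_t = wins$center_t, bands = bands$band,
       conditions = conds, directions = c("A->B", "B->A"),
       networks = c(nmA, nmB), measure = measure)
}

#' MVAR-model-implied band power over sliding windows
#'
#' Fits sliding-window MVAR models per fitting band (pooling the trials
#' of one condition), evaluates the model spectrum diagonal `S[m,m](f)`
#' on a 1 Hz grid, converts to dB, z-scores along time per (channel,
#' frequency) and averages into the six analysis bands. Used to check
#' that the MVAR models reproduce the band-power dynamics estimated by
#' the STFT.
#'
#' @param trials a `trial_tensor`.
#' @param condition which condition's trials to pool (default
#'   `"ext2int"`).
#' @param fit_bands fitting bands and orders (default
#'   [mvar_fit_bands()]).
#' @param win_s,step_s,crop sliding-window geometry.
#' @return list with `power` (time x band x channel, z-score units) and
#'   `center_t` (s).
#' @export
mvar_band_power <- function(trials, condition = "ext2int",
                            fit_bands = mvar_fit_bands(),
                            win_s = 0.5, step_s = 0.125,
                            crop = c(-2.3, 2.3)) {
  stopifnot(inherits(trials, "trial_tensor"))
  bands <- analysis_bands()
  split_tr <- band_split(trials, fit_bands)
  wins <- sliding_windows(trials$time, trials$fs, win_s, step_s, crop)
  nwin <- length(wins$start)
  k <- dim(trials$data)[2]
  acc <- array(0, c(nwin, nrow(bands), k),
               dimnames = list(NULL, bands$band, NULL))
  nfreq <- numeric(nrow(bands))
  for (bt in split_tr) {
    lo <- max(1, ceiling(bt$band[1])); hi <- floor(bt$band[2])
    freqs <- seq(lo, hi)
    freqs <- freqs[freqs <= trials$fs / 2 - 1]
    if (!length(freqs)) next
    sel <- bt$condition == condition
    pw <- array(NA_real_, c(nwin, length(freqs), k))
    for (w in seq_len(nwin)) {
      idx <- wins$start[w]:(wins$start[w] + wins$len - 1L)
      model <- fit_mvar(bt$data[idx, , sel, drop = FALSE], bt$order,
                        trials$fs)
      pw[w, , ] <- t(mvar_spectrum(model, freqs))
    }
    pw <- 10 * log10(pw + 1e-300)
    for (ch in seq_len(k)) for (fi in seq_along(freqs)) {
      v <- pw[, fi, ch]
      s <- stats::sd(v)
      pw[, fi, ch] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
    for (b in seq_len(nrow(bands))) {
      fsel <- band_bins(freqs, bands$band[b], bands$lo[b], bands$hi[b])
      if (!any(fsel)) next
      acc[, b, ] <- acc[, b, ] +
        apply(pw[, fsel, , drop = FALSE], c(1, 3), mean) * sum(fsel)
      nfreq[b] <- nfreq[b] + sum(fsel)
    }
  }
  for (b in seq_len(nrow(bands)))
    acc[, b, ] <- if (nfreq[b] == 0) NA_real_ else acc[, b, ] / nfreq[b]
  list(power = acc, center_t = wins$center_t)
}

#' Phase-locking value
#'
#' Decomposes each trial into 2 Hz non-overlapping bands (zero-phase
#' 6th-order Butterworth), extracts instantaneous phases with the
#' Hilbert transform over the full epoch, and computes across-trial
#' phase locking `PLV(m,n,t,f,c) = |mean_tr exp(i (phi_m - phi_n))|`
#' per channel pair, time point and band; bands are then averaged into
#' the six analysis bands and the time axis decimated to the band-power
#' step.
#'
#' @param trials a `trial_tensor`.
#' @param fmax upper frequency bound (default 120 Hz; must be below
#'   Nyquist).
#' @param bin_hz narrow-band width (default 2 Hz).
#' @param step_s output time step (default the 31.25 ms band-power step).
#' @return list with `plv` (array pair x time x band x condition),
#'   `pairs` (2-column matrix of channel indices), `time`, `bands`.
#' @export
plv <- function(trials, fmax = 120, bin_hz = 2, step_s = RBP_STEP_S) {
  stopifnot(inherits(trials, "trial_tensor"))
  fs <- trials$fs
  if (fmax >= fs / 2) stop("requested band exceeds the Nyquist frequency")
  d <- dim(trials$data)
  k <- d[2]
  conds <- c("ext2int", "int2ext")
  for (cond in conds)
    if (sum(trials$condition == cond) < 2 && any(trials$condition == cond))
      stop("need at least 2 trials per condition")
  step <- as.integer(round(step_s * fs))
  tsel <- seq(1L, d[1], by = step)
  bands <- analysis_bands()
  edges <- seq(0, fmax, by = bin_hz)
  nbin <- length(edges) - 1L
  centers_f <- (edges[-1] + edges[-length(edges)]) / 2
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pairs <- cbind(pairs[, 2], pairs[, 1]) # (m, n) with m < n
  npair <- nrow(pairs)
  nt <- length(tsel)
  acc <- array(0, c(npair, nt, nrow(bands), 2))
  bincount <- numeric(nrow(bands))
  x2 <- matrix(trials$data, nrow = d[1]) # time x (ch*trial)
  for (bi in seq_len(nbin)) {
    lo <- max(edges[bi], 0.1); hi <- edges[bi + 1]
    xf <- if (bi == 1) zerophase_filter(x2, fs, "low", hi)
          else zerophase_filter(x2, fs, "pass", c(lo, hi))
    ph <- Arg(analytic_signal(xf))
    ph <- array(ph, d)[tsel, , , drop = FALSE]
    b_of <- which(vapply(seq_len(nrow(bands)), function(b)
      centers_f[bi] >= bands$lo[b] && centers_f[bi] <= bands$hi[b] &&
        !(bands$band[b] == "hgb" &&
            any(vapply(notch_ranges(), function(nr)
              centers_f[bi] > nr[1] && centers_f[bi] < nr[2], logical(1)))),
      logical(1)))
    if (!length(b_of)) next
    for (ci in 1:2) {
      sel <- trials$condition == conds[ci]
      if (!any(sel)) next
      for (pi in seq_len(npair)) {
        dphi <- ph[, pairs[pi, 1], sel] - ph[, pairs[pi, 2], sel]
        v <- Mod(rowMeans(exp(1i * dphi)))
        for (b in b_of) acc[pi, , b, ci] <- acc[pi, , b, ci] + v
      }
    }
    for (b in b_of) bincount[b] <- bincount[b] + 1
  }
  for (b in seq_len(nrow(bands))) {
    if (bincount[b] == 0) acc[, , b, ] <- NA_real_
    else acc[, , b, ] <- acc[, , b, ] / bincount[b]
  }
  list(plv = acc, pairs = pairs, time = trials$time[tsel],
       bands = bands$band, conditions = conds)
}

#' Across-subject connectivity statistics
#'
#' Per time step and band, a two-sided Wilcoxon rank-sum test between
#' conditions across subjects' network-mean connectivity values,
#' FDR-corrected jointly across time steps and bands.
#'
#' @param subject_series list (one element per subject, at least 5) of
#'   matrices time x band for condition 1 and condition 2: supply as
#'   `list(ext2int = list(...), int2ext = list(...))`.
#' @param alpha FDR level (default 0.001).
#' @return time x band logical significance mask.
#' @export
connectivity_group_stats <- function(subject_series, alpha = 0.001) {
  s1 <- subject_series$ext2int
  s2 <- subject_series$int2ext
  if (length(s1) < 5) stop("need at least 5 subjects")
  if (length(s1) != length(s2)) stop("conditions must share the subjects")
  nt <- nrow(s1[[1]]); nb <- ncol(s1[[1]])
  x <- t(vapply(s1, function(m) as.numeric(m), numeric(nt * nb)))
  y <- t(vapply(s2, function(m) as.numeric(m), numeric(nt * nb)))
  p <- rank_sum_test(x, y)
  adj <- fdr_adjust(p, alpha)
  matrix(adj$rejected, nt, nb, dimnames = dimnames(s1[[1]]))
}
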