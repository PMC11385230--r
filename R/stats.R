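# Condition-difference statistics: SNR-like strength of the band-power
# difference, vectorized two-sample rank-sum tests, Benjamini-Hochberg
# FDR, temporal-continuity screening, crossover timing and between-group
# crossover comparisons.

#' Strength of the band-power difference between conditions
#'
#' For each time step, band and channel, the variance of the two
#' condition means divided by the mean of the two within-condition
#' trial-by-trial variances (sample-variance convention, denominator
#' n-1, for both). The summary per (band, channel) is
#' `10*log10` of the time-mean of this ratio over the analysis crop.
#' Channels with zero trial variance in both conditions are reported as
#' missing; a zero numerator yields the -120 dB sentinel.
#'
#' @param rbp an `rbp_tensor` (see [epoch_rbp()]).
#' @param crop time interval (s) over which the summary is averaged.
#' @return list with `snr_t` (time x band x channel ratio, linear),
#'   `snr_db` (band x channel summary, dB), `time`, `bands`.
#' @export
rbp_snr <- function(rbp, crop = c(-2.3, 2.3)) {
  stopifnot(inherits(rbp, "rbp_tensor"))
  conds <- c("ext2int", "int2ext")
  sel1 <- rbp$condition == conds[1]
  sel2 <- rbp$condition == conds[2]
  if (sum(sel1) < 2 || sum(sel2) < 2)
    stop("need at least 2 trials per condition")
  d <- dim(rbp$rbp)
  m1 <- apply(rbp$rbp[, , , sel1, drop = FALSE], c(1, 2, 3), mean)
  m2 <- apply(rbp$rbp[, , , sel2, drop = FALSE], c(1, 2, 3), mean)
  v1 <- apply(rbp$rbp[, , , sel1, drop = FALSE], c(1, 2, 3), stats::var)
  v2 <- apply(rbp$rbp[, , , sel2, drop = FALSE], c(1, 2, 3), stats::var)
  num <- (m1 - m2)^2 / 2          # sample variance of the 2 condition means
  den <- (v1 + v2) / 2
  ratio <- num / den
  ratio[den == 0] <- NA_real_
  tsel <- rbp$time >= crop[1] & rbp$time <= crop[2]
  nb <- d[2]; k <- d[3]
  snr_db <- matrix(NA_real_, nb, k, dimnames = list(rbp$bands, NULL))
  for (b in seq_len(nb)) for (ch in seq_len(k)) {
    mval <- mean(ratio[tsel, b, ch])
    if (is.na(mval)) next
    snr_db[b, ch] <- if (mval <= 0) -120 else 10 * log10(mval)
  }
  list(snr_t = ratio, snr_db = snr_db, time = rbp$time, bands = rbp$bands)
}

#' Vectorized two-sided Wilcoxon rank-sum test
#'
#' Tests each column of `x` against the corresponding column of `y`.
#' Uses the normal approximation with tie correction and continuity
#' correction; when both samples have fewer than 10 observations and no
#' ties are present, the exact null distribution is used instead.
#'
#' @param x numeric matrix (n1 x m) — or vector for a single test.
#' @param y numeric matrix (n2 x m).
#' @return numeric vector of m two-sided p-values.
#' @export
rank_sum_test <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  stopifnot(ncol(x) == ncol(y))
  n1 <- nrow(x); n2 <- nrow(y); m <- ncol(x)
  p <- numeric(m)
  z <- rbind(x, y)
  rk <- apply(z, 2, rank)
  w <- colSums(rk[seq_len(n1), , drop = FALSE]) # rank sum of x
  u <- w - n1 * (n1 + 1) / 2
  has_ties <- apply(z, 2, function(col) anyDuplicated(col) > 0)
  exact_ok <- n1 < 10 && n2 < 10
  for (j in seq_len(m)) {
    if (exact_ok && !has_ties[j]) {
      p[j] <- min(1, 2 * min(stats::pwilcox(u[j], n1, n2),
                             1 - stats::pwilcox(u[j] - 1, n1, n2)))
    } else {
      mu <- n1 * n2 / 2
      tie_tab <- table(z[, j])
      tiecorr <- sum(tie_tab^3 - tie_tab) /
        ((n1 + n2) * (n1 + n2 - 1))
      sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tiecorr)
      if (sigma2 <= 0) { p[j] <- 1; next }
      zstat <- (u[j] - mu - sign(u[j] - mu) * 0.5) / sqrt(sigma2)
      p[j] <- 2 * stats::pnorm(-abs(zstat))
    }
  }
  pmin(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR adjustment; also returns the rejection set at level `q`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` (monotone adjusted p-values) and
#'   `rejected` (logical vector).
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (length(p) == 0) return(list(adjusted = numeric(0), rejected = logical(0)))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

# Longest run of TRUE values in a logical vector.
run_lengths <- function(flag) {
  if (!any(flag)) return(integer(0))
  r <- rle(flag)
  r$lengths[r$values]
}

#' Channel-level significance with FDR and temporal continuity
#'
#' Per time step, band and channel, a two-sided Wilcoxon rank-sum test
#' across trials between the two switching conditions; the p-values of
#' all supplied subjects are FDR-adjusted jointly (across subjects, time
#' steps, bands and channels); a channel is then "significant" in a band
#' iff it retains at least one contiguous run of significant time steps
#' strictly longer than `min_run_ms` (at the 31.25 ms step this means
#' at least 4 consecutive steps).
#'
#' @param rbp_list a single `rbp_tensor` or a list of them (one per
#'   subject).
#' @param alpha FDR level (default 0.05).
#' @param min_run_ms continuity requirement in ms (default 100,
#'   strict inequality).
#' @return list with per-subject elements `sig_mask` (time x band x
#'   channel logical, FDR + continuity surviving steps), `sig_channel`
#'   (band x channel logical), plus the pooled ratios `R_C` (significant
#'   channels in any band / total channels) and `R_S` (subjects with at
#'   least one significant channel / subjects).
#' @export
channel_significance <- function(rbp_list, alpha = 0.05, min_run_ms = 100) {
  if (inherits(rbp_list, "rbp_tensor")) rbp_list <- list(rbp_list)
  pv <- list()
  dims <- list()
  for (s in seq_along(rbp_list)) {
    rbp <- rbp_list[[s]]
    sel1 <- rbp$condition == "ext2int"
    sel2 <- rbp$condition == "int2ext"
    if (sum(sel1) < 2 || sum(sel2) < 2)
      stop("need at least 2 trials per condition")
    d <- dim(rbp$rbp)
    x <- matrix(aperm(rbp$rbp[, , , sel1, drop = FALSE], c(4, 1, 2, 3)),
                nrow = sum(sel1))
    y <- matrix(aperm(rbp$rbp[, , , sel2, drop = FALSE], c(4, 1, 2, 3)),
                nrow = sum(sel2))
    pv[[s]] <- rank_sum_test(x, y)
    dims[[s]] <- d[1:3]
  }
  adj <- fdr_adjust(unlist(pv), alpha)
  res <- list(subjects = vector("list", length(rbp_list)))
  offset <- 0L
  n_sig_ch <- 0L; n_ch <- 0L; n_sig_subj <- 0L
  min_steps <- NULL
  for (s in seq_along(rbp_list)) {
    d <- dims[[s]]
    m <- prod(d)
    rej <- array(adj$rejected[offset + seq_len(m)], d)
    offset <- offset + m
    step_ms <- rbp_list[[s]]$step_s * 1000
    min_steps <- as.integer(floor(min_run_ms / step_ms)) + 1L
    sig_ch <- matrix(FALSE, d[2], d[3],
                     dimnames = list(rbp_list[[s]]$bands, NULL))
    for (b in seq_len(d[2])) for (ch in seq_len(d[3])) {
      runs <- run_lengths(rej[, b, ch])
      sig_ch[b, ch] <- any(runs >= min_steps)
      if (!sig_ch[b, ch]) rej[, b, ch] <- FALSE
      else {
        # keep only surviving runs
        r <- rle(rej[, b, ch])
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (j in which(r$values & r$lengths < min_steps))
          rej[starts[j]:ends[j], b, ch] <- FALSE
      }
    }
    res$subjects[[s]] <- list(sig_mask = rej, sig_channel = sig_ch)
    n_ch <- n_ch + d[3]
    n_sig_ch <- n_sig_ch + sum(apply(sig_ch, 2, any))
    if (any(sig_ch)) n_sig_subj <- n_sig_subj + 1L
  }
  res$R_C <- n_sig_ch / n_ch
  res$R_S <- n_sig_subj / length(rbp_list)
  res$alpha <- alpha
  res$min_steps <- min_steps
  res
}

#' Network-level significance
#'
#' For each network, band and time step, a two-sided Wilcoxon rank-sum
#' test between the two conditions across the trial-averaged values of
#' the network's channels, FDR-corrected jointly across networks, bands
#' and time steps (default level 0.001). Only channels flagged
#' significant at channel level should be supplied.
#'
#' @param rbp an `rbp_tensor`.
#' @param networks named list mapping network name to channel indices
#'   (each needs at least 2 channels, else that network/band is skipped
#'   with a log entry).
#' @param alpha FDR level (default 0.001).
#' @return list with `masks[[network]]` (time x band logical) and
#'   `skipped` (character log).
#' @export
network_significance <- function(rbp, networks, alpha = 0.001) {
  stopifnot(inherits(rbp, "rbp_tensor"))
  cm <- list(ext2int = rbp$condition == "ext2int",
             int2ext = rbp$condition == "int2ext")
  d <- dim(rbp$rbp)
  skipped <- character(0)
  pv <- c(); meta <- NULL
  for (nw in names(networks)) {
    chs <- networks[[nw]]
    if (length(chs) < 2) {
      skipped <- c(skipped, sprintf("%s: fewer than 2 channels", nw))
      next
    }
    # trial-averaged channel values per condition: time x band x channel
    a1 <- apply(rbp$rbp[, , chs, cm$ext2int, drop = FALSE], c(1, 2, 3), mean)
    a2 <- apply(rbp$rbp[, , chs, cm$int2ext, drop = FALSE], c(1, 2, 3), mean)
    x <- matrix(aperm(a1, c(3, 1, 2)), nrow = length(chs))
    y <- matrix(aperm(a2, c(3, 1, 2)), nrow = length(chs))
    pv <- c(pv, rank_sum_test(x, y))
    meta <- rbind(meta, data.frame(network = nw, n = d[1] * d[2]))
  }
  masks <- list()
  if (length(pv)) {
    adj <- fdr_adjust(pv, alpha)
    offset <- 0L
    for (i in seq_len(nrow(meta))) {
      m <- meta$n[i]
      masks[[meta$network[i]]] <-
        matrix(adj$rejected[offset + seq_len(m)], d[1], d[2],
               dimnames = list(NULL, rbp$bands))
      offset <- offset + m
    }
  }
  list(masks = masks, skipped = skipped, alpha = alpha)
}

#' Remove the condition-common response
#'
#' Subtracts the across-condition mean from each condition mean; the two
#' residuals are exact mirror images.
#'
#' @param m1,m2 condition-mean time courses (numeric vectors or arrays of
#'   identical shape).
#' @return list with `r1`, `r2` (residuals) and `common` (the mean).
#' @export
subtract_common <- function(m1, m2) {
  common <- (m1 + m2) / 2
  list(r1 = m1 - common, r2 = m2 - common, common = common)
}

#' Crossover time of the condition-specific band power
#'
#' Subtracts the condition-common response, low-pass filters both
#' residuals (1 Hz cutoff, zero-phase Butterworth, order 6) and returns
#' the time of the first sign change of their difference inside the
#' search window, linearly interpolated between the two bracketing time
#' steps. `NA` when no crossing falls inside the window.
#'
#' @param m1,m2 condition-mean time courses (numeric vectors on the
#'   band-power grid).
#' @param time time axis (s) of the same length.
#' @param window allowed crossover interval (default `c(-0.5, 2)` s).
#' @param lowpass_hz smoothing cutoff (default 1 Hz); `NULL` to skip.
#' @return crossover time in seconds, or `NA_real_`.
#' @export
crossover_time <- function(m1, m2, time, window = c(-0.5, 2),
                           lowpass_hz = 1) {
  stopifnot(length(m1) == length(time), length(m2) == length(time))
  fs_rbp <- 1 / mean(diff(time))
  res <- subtract_common(m1, m2)
  r1 <- res$r1; r2 <- res$r2
  if (!is.null(lowpass_hz)) {
    r1 <- zerophase_filter(r1, fs_rbp, "low", lowpass_hz, order = 6)
    r2 <- zerophase_filter(r2, fs_rbp, "low", lowpass_hz, order = 6)
  }
  dd <- r1 - r2
  sel <- which(time >= window[1] & time <= window[2])
  for (i in sel) {
    if (dd[i] == 0) return(time[i])
    if (i == length(dd) || time[i + 1] > window[2] + 1e-9) break
    if (dd[i] * dd[i + 1] < 0) {
      frac <- dd[i] / (dd[i] - dd[i + 1])
      return(time[i] + frac * (time[i + 1] - time[i]))
    }
  }
  NA_real_
}

#' Per-channel crossover estimates
#'
#' Applies [crossover_time()] to every (band, channel) of an
#' `rbp_tensor`, optionally restricted to significant channels.
#'
#' @param rbp an `rbp_tensor`.
#' @param sig_channel optional band x channel logical gate (e.g. from
#'   [channel_significance()]); others are reported `NA`.
#' @param ... passed to [crossover_time()].
#' @return matrix band x channel of crossover times (s), `NA` where
#'   absent.
#' @export
crossover_map <- function(rbp, sig_channel = NULL, ...) {
  cmu <- condition_means(rbp)
  d <- dim(cmu)
  out <- matrix(NA_real_, d[2], d[3], dimnames = list(rbp$bands, NULL))
  for (b in seq_len(d[2])) for (ch in seq_len(d[3])) {
    if (!is.null(sig_channel) && !sig_channel[b, ch]) next
    out[b, ch] <- crossover_time(cmu[, b, ch, 1], cmu[, b, ch, 2],
                                 rbp$time, ...)
  }
  out
}

#' Compare crossover-time distributions between two networks
#'
#' Two-sided Wilcoxon rank-sum test on the channel-wise crossover times
#' of network A vs network B, per band, FDR-corrected across bands;
#' reports the mean difference in ms (A minus B).
#'
#' @param xo_a,xo_b band x channel crossover matrices ([crossover_map()])
#'   for the two networks.
#' @param alpha FDR level (default 0.001).
#' @return data frame per band: `band`, `n_a`, `n_b`, `mean_diff_ms`,
#'   `p`, `p_adj`, `significant`. Bands with an empty distribution are
#'   skipped.
#' @export
compare_crossovers <- function(xo_a, xo_b, alpha = 0.001) {
  stopifnot(nrow(xo_a) == nrow(xo_b))
  bands <- rownames(xo_a)
  rows <- NULL
  for (b in seq_len(nrow(xo_a))) {
    a <- xo_a[b, ]; a <- a[!is.na(a)]
    bb <- xo_b[b, ]; bb <- bb[!is.na(bb)]
    if (length(a) < 2 || length(bb) < 2) next
    p <- rank_sum_test(a, bb)
    rows <- rbind(rows, data.frame(
      band = bands[b], n_a = length(a), n_b = length(bb),
      mean_diff_ms = 1000 * (mean(a) - mean(bb)), p = p,
      stringsAsFactors = FALSE))
  }
  if (is.null(rows)) return(rows)
  adj <- fdr_adjust(rows$p, alpha)
  rows$p_adj <- adj$adjusted
  rows$significant <- adj$rejected
  rows
}
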