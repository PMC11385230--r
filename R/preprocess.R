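# Continuous-recording container and preprocessing: bipolar referencing,
# zero-phase filtering, downsampling, epoching and amplitude-based
# epoch rejection.

#' Continuous multichannel recording
#'
#' @param signal numeric matrix, samples x contacts (µV-like units).
#' @param fs sampling rate, Hz.
#' @param contacts data frame with columns `name`, `shank`, `pos`
#'   (position index on the shank, 1 = deepest), `x`, `y`, `z` (MNI mm)
#'   and optionally `broken` (logical exclusion flag).
#' @param events data frame with columns `onset` (sample index) and
#'   `condition` (`"ext2int"` or `"int2ext"`).
#' @return object of class `ieeg_recording`.
#' @export
ieeg_recording <- function(signal, fs, contacts, events) {
  signal <- as.matrix(signal)
  stopifnot(nrow(contacts) == ncol(signal))
  if (is.null(contacts$broken)) contacts$broken <- FALSE
  if (nrow(events) > 0) {
    stopifnot(all(events$onset >= 1), all(events$onset <= nrow(signal)))
    stopifnot(all(events$condition %in% c("ext2int", "int2ext")))
    stopifnot(!is.unsorted(events$onset))
  }
  structure(list(signal = signal, fs = fs, contacts = contacts,
                 events = events),
            class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d samples x %d contacts @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$events)))
  invisible(x)
}

#' Nearest-neighbor bipolar referencing
#'
#' Forms one output channel per pair of adjacent non-excluded contacts on
#' the same shank, starting from the deepest contact: the channel signal is
#' the deeper contact minus its nearest shallower neighbor, and the channel
#' coordinate is the arithmetic mean of the pair's coordinates. A broken
#' contact breaks adjacency — the contacts on either side of the gap are
#' not paired across it. Shanks with fewer than two usable contacts
#' contribute no channels (with a warning).
#'
#' @param recording an [ieeg_recording] at contact level.
#' @return an [ieeg_recording] whose "contacts" table describes bipolar
#'   channels (columns `name`, `shank`, `pos`, `x`, `y`, `z`).
#' @export
bipolar_reference <- function(recording) {
  stopifnot(inherits(recording, "ieeg_recording"))
  ct <- recording$contacts
  out_sig <- NULL
  out_tab <- NULL
  for (sh in unique(ct$shank)) {
    rows <- which(ct$shank == sh)
    rows <- rows[order(ct$pos[rows])]
    usable <- rows[!ct$broken[rows]]
    if (length(usable) < 2) {
      warning(sprintf("shank %s has fewer than 2 usable contacts; skipped", sh))
      next
    }
    for (i in seq_len(length(usable) - 1L)) {
      a <- usable[i]; b <- usable[i + 1L]
      if (ct$pos[b] != ct$pos[a] + 1L) next # gap (e.g. broken contact)
      out_sig <- cbind(out_sig, recording$signal[, a] - recording$signal[, b])
      out_tab <- rbind(out_tab, data.frame(
        name = paste0(ct$name[a], "-", ct$name[b]), shank = sh,
        pos = ct$pos[a],
        x = (ct$x[a] + ct$x[b]) / 2, y = (ct$y[a] + ct$y[b]) / 2,
        z = (ct$z[a] + ct$z[b]) / 2, broken = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out_sig)) stop("no bipolar channels could be formed")
  ieeg_recording(out_sig, recording$fs, out_tab, recording$events)
}

#' High-pass and notch filtering
#'
#' Applies, per channel, a zero-phase 6th-order Butterworth high-pass
#' (default cutoff 0.1 Hz, removing slow drifts) followed by zero-phase
#' Butterworth band-stop filters at the line frequency and its harmonic
#' (default stop bands 48-52 and 98-102 Hz).
#'
#' @param recording an [ieeg_recording].
#' @param highpass_hz high-pass cutoff (Hz); `NULL` to skip.
#' @param notches list of stop-band edges (Hz).
#' @param order Butterworth order.
#' @return filtered [ieeg_recording].
#' @export
filter_chain <- function(recording, highpass_hz = 0.1,
                         notches = list(c(48, 52), c(98, 102)), order = 6) {
  stopifnot(inherits(recording, "ieeg_recording"))
  x <- recording$signal
  fs <- recording$fs
  for (nb in notches)
    if (max(nb) >= fs / 2)
      stop(sprintf("notch band [%g, %g] Hz infeasible at fs = %g Hz",
                   nb[1], nb[2], fs))
  specs <- list()
  if (!is.null(highpass_hz))
    specs <- c(specs, list(list(type = "high", edges = highpass_hz,
                                order = order)))
  for (nb in notches)
    specs <- c(specs, list(list(type = "stop", edges = nb, order = order)))
  if (length(specs)) recording$signal <- zerophase_filter(x, fs, specs)
  recording
}

#' Downsample a recording by an integer factor
#'
#' Anti-alias low-pass filters (zero-phase Butterworth, cutoff at 70% of
#' the target Nyquist, order 12, preserving the 0.1-120 Hz analysis band
#' within 1%) and decimates. Event onsets are rescaled.
#'
#' @param recording an [ieeg_recording].
#' @param target_fs target sampling rate (Hz); the original rate must be
#'   an integer multiple of it.
#' @return downsampled [ieeg_recording].
#' @export
downsample <- function(recording, target_fs = 512) {
  stopifnot(inherits(recording, "ieeg_recording"))
  fs <- recording$fs
  if (fs == target_fs) return(recording)
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("fs = %g is not an integer multiple of target %g", fs, target_fs))
  ratio <- as.integer(round(ratio))
  x <- zerophase_filter(recording$signal, fs, "low", 0.7 * target_fs / 2,
                        order = 12)
  idx <- seq(1L, nrow(x), by = ratio)
  ev <- recording$events
  if (nrow(ev) > 0) ev$onset <- pmax(1L, as.integer(ceiling(ev$onset / ratio)))
  ieeg_recording(x[idx, , drop = FALSE], target_fs, recording$contacts, ev)
}

#' Extract switch trials
#'
#' Epochs the continuous signal around each event into the trial tensor
#' `D(t, ch, tr)` with t = 0 at the event onset. Epochs are half-open
#' `[onset + span[1]*fs, onset + span[2]*fs)` in samples; epochs exceeding
#' the session bounds are dropped with a warning.
#'
#' @param recording an [ieeg_recording] (typically bipolar-referenced).
#' @param span trial window in seconds relative to the event
#'   (default `c(-4, 4)`).
#' @param max_per_condition cap on trials per condition (default 60).
#' @return object of class `trial_tensor`: list with `data` (array
#'   time x channels x trials), `time` (s, relative to the switch),
#'   `fs`, `condition` (per trial), `onsets` (event sample per trial),
#'   `channels` (channel table) and `mask` (NULL until
#'   [reject_epochs()] is applied).
#' @export
extract_trials <- function(recording, span = c(-4, 4),
                           max_per_condition = 60) {
  stopifnot(inherits(recording, "ieeg_recording"))
  fs <- recording$fs
  ev <- recording$events
  if (nrow(ev) == 0) stop("recording has no events")
  n_pre <- as.integer(round(-span[1] * fs))
  n_post <- as.integer(round(span[2] * fs))
  n <- nrow(recording$signal)
  keep <- ev$onset - n_pre >= 1 & ev$onset + n_post - 1 <= n
  if (any(!keep))
    warning(sprintf("%d trial(s) exceed the session bounds; dropped",
                    sum(!keep)))
  ev <- ev[keep, , drop = FALSE]
  sel <- unlist(lapply(split(seq_len(nrow(ev)), ev$condition),
                       utils::head, max_per_condition))
  ev <- ev[sort(sel), , drop = FALSE]
  for (cond in c("ext2int", "int2ext"))
    if (!any(ev$condition == cond))
      stop(sprintf("no extractable trials for condition %s", cond))
  nt <- n_pre + n_post
  k <- ncol(recording$signal)
  dat <- array(NA_real_, c(nt, k, nrow(ev)))
  for (i in seq_len(nrow(ev))) {
    a <- ev$onset[i] - n_pre
    dat[, , i] <- recording$signal[a:(a + nt - 1L), ]
  }
  structure(list(
    data = dat,
    time = (seq_len(nt) - 1L - n_pre) / fs,
    fs = fs,
    condition = ev$condition,
    onsets = ev$onset,
    channels = recording$contacts,
    mask = NULL
  ), class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf("<trial_tensor> %d samples x %d channels x %d trials @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Amplitude-based epoch rejection
#'
#' Flags samples whose amplitude deviates more than `sd_threshold`
#' standard deviations from the mean, with mean and SD computed per
#' channel on the continuous session signal (not per epoch). Contiguous
#' supra-threshold runs are extended by `margin_ms` on each side. Whole
#' trials are never dropped; the result is a boolean rejection mask on
#' the trial tensor (`TRUE` = sample excluded from averages).
#'
#' @param recording the continuous [ieeg_recording] the trials came from.
#' @param trials the [extract_trials()] output.
#' @param sd_threshold rejection threshold in SD multiples (default 6).
#' @param margin_ms margin added to each side of a run (default 100 ms).
#' @return the `trial_tensor` with its `mask` slot filled
#'   (time x channels x trials logical array).
#' @export
reject_epochs <- function(recording, trials, sd_threshold = 6,
                          margin_ms = 100) {
  stopifnot(inherits(recording, "ieeg_recording"),
            inherits(trials, "trial_tensor"))
  x <- recording$signal
  n <- nrow(x); k <- ncol(x)
  fs <- recording$fs
  margin <- as.integer(round(margin_ms / 1000 * fs))
  sess_mask <- matrix(FALSE, n, k)
  for (ch in seq_len(k)) {
    mu <- mean(x[, ch]); sdv <- stats::sd(x[, ch])
    if (sdv == 0) {
      warning(sprintf("channel %d has zero variance; empty mask", ch))
      next
    }
    bad <- abs(x[, ch] - mu) > sd_threshold * sdv
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- max(1L, starts[j] - margin)
      b <- min(n, ends[j] + margin)
      sess_mask[a:b, ch] <- TRUE
    }
  }
  nt <- dim(trials$data)[1]
  n_pre <- sum(trials$time < 0)
  mask <- array(FALSE, dim(trials$data))
  for (i in seq_along(trials$onsets)) {
    a <- trials$onsets[i] - n_pre
    mask[, , i] <- sess_mask[a:(a + nt - 1L), , drop = FALSE]
  }
  trials$mask <- mask
  trials
}
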