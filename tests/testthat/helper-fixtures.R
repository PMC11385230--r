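# Shared fixtures, all generated in code.

# A minimal noise recording with evenly spaced events on the 16-sample grid.
noise_recording <- function(n_s = 120, k = 2, fs = 512, n_events = 8,
                            seed = 1) {
  set.seed(seed)
  n <- n_s * fs
  sig <- matrix(rnorm(n * k), n, k)
  contacts <- data.frame(name = paste0("c", seq_len(k)), shank = "S",
                         pos = seq_len(k), x = 0, y = 0, z = 0,
                         broken = FALSE)
  onsets <- 1L + 16L * as.integer(round(seq(5, n_s - 5,
                                            length.out = n_events) * fs / 16))
  events <- data.frame(onset = onsets,
                       condition = rep(c("ext2int", "int2ext"),
                                       length.out = n_events))
  ieeg_recording(sig, fs, contacts, events)
}

# Build an rbp_tensor directly (bypassing the spectral stage) for unit
# tests of the statistics layer.
make_rbp_tensor <- function(arr, time, bands, condition) {
  structure(list(rbp = arr, time = time, bands = bands,
                 condition = condition,
                 channels = data.frame(name = paste0("ch", seq_len(dim(arr)[3]))),
                 step_s = mean(diff(time))),
            class = "rbp_tensor")
}

# Build a trial_tensor directly.
make_trial_tensor <- function(dat, fs = 512, condition = NULL, time = NULL) {
  d <- dim(dat)
  if (is.null(time)) time <- (seq_len(d[1]) - 1 - d[1] / 2) / fs
  if (is.null(condition))
    condition <- rep(c("ext2int", "int2ext"), length.out = d[3])
  structure(list(data = dat, time = time, fs = fs, condition = condition,
                 onsets = NULL,
                 channels = data.frame(name = paste0("ch", seq_len(d[2]))),
                 mask = NULL),
            class = "trial_tensor")
}

# Simulate a stationary VAR process as trials (burn-in discarded).
simulate_var <- function(A, sigma, n, ntrials, burn = 100) {
  k <- dim(A)[1]; p <- dim(A)[3]
  out <- array(0, c(n, k, ntrials))
  for (tr in seq_len(ntrials)) {
    x <- matrix(0, n + burn, k)
    for (t in (p + 1):(n + burn)) {
      v <- rnorm(k, sd = sigma)
      for (l in seq_len(p)) v <- v + A[, , l] %*% x[t - l, ]
      x[t, ] <- v
    }
    out[, , tr] <- x[burn + seq_len(n), ]
  }
  out
}

# Brute-force Benjamini-Hochberg step-up oracle: returns the rejection set.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0L
  for (i in seq_len(m)) if (ps[i] <= i / m * q) kmax <- i
  rej <- logical(m)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}
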