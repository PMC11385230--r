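# Ground-truth recovery experiments on synthetic cohorts. These are the
# package's built-in validation studies: estimator agreement between the
# STFT and wavelet band-power paths, spectral fidelity of the sliding
# MVAR models, and recovery of a planted between-network crossover lag.

#' Agreement between STFT and wavelet band power
#'
#' Generates one synthetic subject with smooth planted band-limited power
#' modulations in all six bands, runs both spectral estimators with the
#' band-dependent windows and session z-scoring, and correlates the
#' group-mean condition-mean band-power time courses over the analysis
#' crop, per band, condition and channel group.
#'
#' @param n_channels_per_network channels per group (default 10, i.e. 20
#'   channels in total).
#' @param n_trials trials per condition (default 60).
#' @param seed generator seed.
#' @return list with `mean_r` (mean Pearson correlation across bands,
#'   conditions and groups) and `per_cell` (the individual correlations).
#' @export
agreement_stft_wavelet <- function(n_channels_per_network = 10,
                                   n_trials = 60, seed = 1) {
  cfg <- gen_config(n_subjects = 1,
                    n_channels_per_network = n_channels_per_network,
                    n_trials_per_condition = n_trials, seed = seed)
  co <- generate_cohort(cfg)
  bip <- filter_chain(bipolar_reference(co$recordings[[1]]))
  cm1 <- condition_means(epoch_rbp(session_rbp(bip, estimator = "stft"),
                                   max_per_condition = n_trials))
  cm2 <- condition_means(epoch_rbp(session_rbp(bip, estimator = "wavelet"),
                                   max_per_condition = n_trials))
  grp <- co$ground_truth$subjects[[1]]$group_of_channel
  rs <- c()
  for (b in seq_len(dim(cm1)[2])) for (ci in 1:2)
    for (g in unique(grp)) {
      sel <- grp == g
      rs <- c(rs, stats::cor(rowMeans(cm1[, b, sel, ci, drop = FALSE]),
                             rowMeans(cm2[, b, sel, ci, drop = FALSE])))
    }
  list(mean_r = mean(rs), per_cell = rs)
}

#' Spectral fidelity of the sliding-window MVAR models
#'
#' Generates trials from band-limited autoregressive oscillators with
#' strong, slow, trial-locked envelope modulation, fits MVAR models in
#' 500 ms windows stepped 125 ms per fitting band, derives band power
#' from the model spectrum diagonal, and correlates it with the STFT
#' band-power time course per band and channel group.
#'
#' @param n_channels_per_network channels per group (default 3).
#' @param n_trials trials per condition (default 60).
#' @param seed generator seed.
#' @return list with `mean_r` and `per_cell`.
#' @export
mvar_spectral_fidelity <- function(n_channels_per_network = 3,
                                   n_trials = 60, seed = 1) {
  cfg <- gen_config(n_subjects = 1,
                    n_channels_per_network = n_channels_per_network,
                    n_trials_per_condition = n_trials,
                    mode = "ar", background_sd = 0.2, seed = seed)
  co <- generate_cohort(cfg)
  bip <- filter_chain(bipolar_reference(co$recordings[[1]]))
  tr <- extract_trials(bip, max_per_condition = n_trials)
  mbp <- mvar_band_power(tr, "ext2int")
  rbp <- epoch_rbp(session_rbp(bip), max_per_condition = n_trials)
  cm <- condition_means(rbp)
  grp <- co$ground_truth$subjects[[1]]$group_of_channel
  # sample the band-power time course at the sliding-window centers
  idx <- vapply(mbp$center_t, function(tt) which.min(abs(rbp$time - tt)),
                integer(1))
  rs <- c()
  for (b in seq_len(dim(cm)[2])) for (g in unique(grp)) {
    sel <- grp == g
    a <- rowMeans(mbp$power[, b, sel, drop = FALSE])
    d <- rowMeans(cm[idx, b, sel, 1, drop = FALSE])
    rs <- c(rs, stats::cor(a, d))
  }
  list(mean_r = mean(rs), per_cell = rs)
}

#' Recovery of a planted between-network crossover lag
#'
#' Plants a high-gamma band-power crossover at `base_s` in group NetA and
#' `base_s + lag_s` in group NetB, runs the spectral and crossover stages,
#' and returns the recovered mean between-group difference of channel-mean
#' crossover times, averaged over independent cohorts.
#'
#' @param lag_s planted lag in seconds (default 0.22).
#' @param base_s NetA crossover time (default 0.5).
#' @param n_seeds number of independent cohorts (default 20).
#' @param n_channels_per_network channels per group (default 10).
#' @param n_trials trials per condition (default 60).
#' @param seed base seed; cohort i uses `seed + i`.
#' @return list with `mean_diff_ms` (recovered NetB minus NetA lag, ms)
#'   and `per_seed` (ms).
#' @export
crossover_lag_recovery <- function(lag_s = 0.22, base_s = 0.5, n_seeds = 20,
                                   n_channels_per_network = 10,
                                   n_trials = 60, seed = 1) {
  bm <- data.frame(band = "hgb", lo = 52, hi = 118, amplitude = 0.6,
                   contrast = 1.0, crossover = base_s, lag_netb = lag_s,
                   width = 0.3)
  diffs <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- gen_config(n_subjects = 1,
                      n_channels_per_network = n_channels_per_network,
                      n_trials_per_condition = n_trials,
                      band_modulations = bm, seed = seed + i)
    co <- generate_cohort(cfg)
    bip <- filter_chain(bipolar_reference(co$recordings[[1]]))
    sess <- session_rbp(bip, bands = analysis_bands()[6, , drop = FALSE])
    rbp <- epoch_rbp(sess, max_per_condition = n_trials)
    xo <- crossover_map(rbp)
    grp <- co$ground_truth$subjects[[1]]$group_of_channel
    diffs[i] <- 1000 * (mean(xo["hgb", grp == "NetB"], na.rm = TRUE) -
                          mean(xo["hgb", grp == "NetA"], na.rm = TRUE))
  }
  list(mean_diff_ms = mean(diffs), per_seed = diffs)
}
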