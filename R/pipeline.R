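# End-to-end orchestration: simulate -> preprocess -> localize -> band
# power -> statistics -> connectivity, with subject selection and a
# machine-readable summary.

#' Pipeline configuration
#'
#' @param gen a [gen_config()] describing the synthetic cohort.
#' @param alpha_channel channel-level FDR level (default 0.05).
#' @param alpha_network network-level FDR level (default 0.001).
#' @param min_run_ms temporal-continuity requirement (default 100 ms).
#' @param sd_threshold epoch-rejection threshold (default 6 SD).
#' @param tolerance_mm atlas assignment tolerance (default 10 mm).
#' @param min_sig_channels subject-selection rule: minimum significant
#'   channels per network (default 5).
#' @param crop analysis crop (default `c(-2.3, 2.3)` s).
#' @param measures directed-connectivity measures to run.
#' @param connectivity_bands subset of [mvar_fit_bands()] rows to fit
#'   (default all four).
#' @param reject logical: apply amplitude-based epoch rejection.
#' @return a `run_config` list.
#' @export
run_config <- function(gen = gen_config(),
                       alpha_channel = 0.05, alpha_network = 0.001,
                       min_run_ms = 100, sd_threshold = 6,
                       tolerance_mm = 10, min_sig_channels = 5,
                       crop = c(-2.3, 2.3),
                       measures = "dtf",
                       connectivity_bands = mvar_fit_bands(),
                       reject = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Subject selection for connectivity
#'
#' Keeps subjects having at least `min_sig` channels significant (in any
#' band) in each of the two networks.
#'
#' @param sig_by_subject list per subject: `sig_channel` band x channel
#'   logical matrix (from [channel_significance()]).
#' @param network_of list per subject: character vector giving each
#'   channel's network (`NA` for unassigned).
#' @param networks the two network names (default `c("DMN", "DAN")`).
#' @param min_sig minimum significant channels per network (default 5).
#' @return integer vector of selected subject indices; errors with
#'   per-subject counts when empty.
#' @export
select_subjects <- function(sig_by_subject, network_of,
                            networks = c("DMN", "DAN"), min_sig = 5) {
  counts <- t(vapply(seq_along(sig_by_subject), function(s) {
    anyband <- apply(sig_by_subject[[s]]$sig_channel, 2, any)
    vapply(networks, function(nw)
      sum(anyband & !is.na(network_of[[s]]) & network_of[[s]] == nw),
      numeric(1))
  }, numeric(length(networks))))
  keep <- which(apply(counts >= min_sig, 1, all))
  if (!length(keep)) {
    msg <- paste(sprintf("subject %d: %s", seq_len(nrow(counts)),
                         apply(counts, 1, paste, collapse = "/")),
                 collapse = "; ")
    stop("no subject passes the selection rule (significant channels ",
         paste(networks, collapse = "/"), "): ", msg)
  }
  keep
}

#' Run the full analysis on a synthetic cohort
#'
#' Simulates the cohort, preprocesses each subject (bipolar referencing,
#' filtering, optional epoch rejection), assigns channels to networks
#' with the synthetic atlas, computes band power, channel- and
#' network-level significance, SNR and crossover statistics, and — for
#' subjects passing the selection rule — inter-network directed
#' connectivity and PLV, with across-subject statistics when at least
#' five subjects qualify.
#'
#' @param config a [run_config()].
#' @return list (report bundle) with per-stage results and a
#'   JSON-serializable `summary`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$gen)
  atlas <- synthetic_atlas()
  n_subj <- length(cohort$recordings)
  rbp_list <- vector("list", n_subj)
  net_of <- vector("list", n_subj)
  trials_list <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    rec <- cohort$recordings[[s]]
    bip <- bipolar_reference(rec)
    bip <- filter_chain(bip)
    assign <- assign_channels(as.matrix(bip$contacts[, c("x", "y", "z")]),
                              atlas, config$tolerance_mm)
    net_of[[s]] <- assign$label
    sess <- session_rbp(bip)
    rbp <- epoch_rbp(sess, crop = config$crop,
                     max_per_condition = config$gen$n_trials_per_condition)
    if (config$reject) {
      tr <- extract_trials(bip, max_per_condition =
                             config$gen$n_trials_per_condition)
      tr <- reject_epochs(bip, tr, config$sd_threshold)
      rbp <- mask_rbp(rbp, tr, sess)
    }
    rbp_list[[s]] <- rbp
    trials_list[[s]] <- bip
  }
  sig <- channel_significance(rbp_list, config$alpha_channel,
                              config$min_run_ms)
  snr <- lapply(rbp_list, rbp_snr, crop = config$crop)
  crossovers <- lapply(seq_len(n_subj), function(s)
    crossover_map(rbp_list[[s]], sig$subjects[[s]]$sig_channel))
  net_masks <- lapply(seq_len(n_subj), function(s) {
    networks <- list()
    for (nw in c("DMN", "DAN")) {
      chs <- which(!is.na(net_of[[s]]) & net_of[[s]] == nw &
                     apply(sig$subjects[[s]]$sig_channel, 2, any))
      if (length(chs) >= 2) networks[[nw]] <- chs
    }
    if (length(networks))
      network_significance(rbp_list[[s]], networks, config$alpha_network)
    else list(masks = list(), skipped = "no network with >= 2 significant channels")
  })
  sel <- tryCatch(
    select_subjects(sig$subjects, net_of, min_sig = config$min_sig_channels),
    error = function(e) integer(0))
  conn <- list()
  for (s in sel) {
    groups <- list(DMN = which(!is.na(net_of[[s]]) & net_of[[s]] == "DMN"),
                   DAN = which(!is.na(net_of[[s]]) & net_of[[s]] == "DAN"))
    tr <- extract_trials(trials_list[[s]],
                         max_per_condition = config$gen$n_trials_per_condition)
    conn[[length(conn) + 1L]] <- lapply(config$measures, function(msr)
      sliding_connectivity(tr, groups, msr,
                           fit_bands = config$connectivity_bands,
                           crop = config$crop))
  }
  truth_recovery <- recovery_scores(cohort, crossovers)
  summary <- list(
    n_subjects = n_subj,
    R_C = sig$R_C, R_S = sig$R_S,
    selected_subjects = sel,
    snr_db = lapply(snr, `[[`, "snr_db"),
    crossovers = crossovers,
    recovery = truth_recovery,
    seed = config$gen$seed
  )
  list(cohort = cohort, rbp = rbp_list, significance = sig, snr = snr,
       crossovers = crossovers, network_masks = net_masks,
       connectivity = conn, selected = sel, summary = summary,
       config = config)
}

# Score recovered crossovers against the planted ground truth.
recovery_scores <- function(cohort, crossovers) {
  errs <- c()
  for (s in seq_along(crossovers)) {
    truth <- cohort$ground_truth$subjects[[s]]$crossovers
    if (is.null(truth)) next
    est <- crossovers[[s]]
    for (i in seq_len(nrow(truth))) {
      b <- truth$band[i]; ch <- truth$channel[i]
      if (is.na(ch) || !(b %in% rownames(est))) next
      e <- est[b, ch]
      if (!is.na(e)) errs <- c(errs, abs(e - truth$crossover[i]))
    }
  }
  if (!length(errs)) return(list(n = 0L))
  list(n = length(errs), mean_abs_error_s = mean(errs),
       rmse_s = sqrt(mean(errs^2)))
}

# Apply a sample-level rejection mask to a band-power tensor: a band-power
# time step is masked when any raw sample within half a step of its center
# is masked; masked cells are replaced by that trial's channel/band mean
# over the clean steps so trial averages exclude them gracefully.
mask_rbp <- function(rbp, trials, sess) {
  if (is.null(trials$mask)) return(rbp)
  d <- dim(rbp$rbp)
  ntr <- min(d[4], dim(trials$mask)[3])
  half <- rbp$step_s / 2
  cell_of <- lapply(seq_len(d[1]), function(j)
    which(trials$time >= rbp$time[j] - half & trials$time < rbp$time[j] + half))
  for (i in seq_len(ntr)) {
    for (ch in seq_len(d[3])) {
      m <- trials$mask[, ch, i]
      if (!any(m)) next
      bad <- which(vapply(cell_of, function(idx) any(m[idx]), logical(1)))
      if (!length(bad) || length(bad) == d[1]) next
      for (b in seq_len(d[2])) {
        repl <- mean(rbp$rbp[-bad, b, ch, i])
        rbp$rbp[bad, b, ch, i] <- repl
      }
    }
  }
  rbp
}
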