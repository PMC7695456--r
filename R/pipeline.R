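#' Run the full analysis pipeline on one session
#'
#' Chains every stage on a session bundle (real or synthetic): trial
#' scoring and exclusions, neuropil-coefficient estimation and subtraction
#' with re-baselining, artefact-exclusion masking, trial-wise dF/sigmaF
#' extraction, false-positive-calibrated activation/suppression thresholds,
#' target/background classification, per-trial network metrics, and
#' hit:miss-matched per-type summaries.
#'
#' @param session a `sim_session` (or a compatible list with `trials`,
#'   `targets`, `traces`).
#' @param n_perm_calib permutations for the scaling-factor calibration
#'   (the full procedure uses 10,000; desk-scale analyses use fewer).
#' @param n_perm_match permutations for hit:miss matching.
#' @param seed RNG seed for calibration and matching.
#' @param estimate_neuropil if `FALSE`, skip robust regression and use the
#'   generative coefficient (synthetic sessions only; faster).
#' @param radius_um target-zone lateral radius.
#' @return list with `trials` (scored), `responses`, `thresholds`,
#'   `classification`, `sf_activation`, `sf_suppression`,
#'   `neuropil_coeff`, `type_metrics` (per trial type: mean activated
#'   targets and raw network proportions), `matched` (hit:miss matched
#'   per-type metrics) and `behavior` (per-type behavioural summary).
#' @export
analyze_session <- function(session, n_perm_calib = 1000, n_perm_match = 100,
                            seed = 1L, estimate_neuropil = TRUE,
                            radius_um = 10) {
  tr <- session$traces
  abort_if(is.null(tr), "analyze_session(): session has no traces")
  trials <- score_trials(session$trials)

  excl <- artefact_exclusion_mask(trials$onset_s, tr$volume_times_s)
  excl_samples <- rep(FALSE, length(tr$volume_times_s))
  idx <- excl[excl >= 1 & excl <= length(excl_samples)]
  excl_samples[idx] <- TRUE

  if (estimate_neuropil) {
    coefs <- vapply(seq_len(nrow(tr$f_roi)), function(i) {
      estimate_neuropil_coefficient(tr$f_roi[i, ], tr$f_neuropil[i, ],
                                    exclude_mask = excl_samples)
    }, numeric(1))
    coefs <- fill_unreliable_coefficients(coefs)
  } else {
    coefs <- rep(session$config$neuropil_coeff_true, nrow(tr$f_roi))
  }
  f_cell <- subtract_and_rebaseline(tr$f_roi, tr$f_neuropil, coefs)

  responses <- extract_trial_responses(f_cell, tr$volume_times_s,
                                       trials$onset_s, exclusion = excl)

  cr_idx <- which(trials$trial_type == 0 & trials$outcome == "correct_reject")
  abort_if(length(cr_idx) < 5L,
           "analyze_session(): too few correct-reject catch trials")
  cr <- responses[, cr_idx, drop = FALSE]
  cal_act <- calibrate_scaling_factor(cr, "activation", n_perm = n_perm_calib,
                                      seed = derive_seed(seed, "cal_act"))
  cal_sup <- calibrate_scaling_factor(cr, "suppression", n_perm = n_perm_calib,
                                      seed = derive_seed(seed, "cal_sup"))
  thr <- compute_thresholds(cr, cal_act$scaling_factor, cal_sup$scaling_factor)
  cls <- classify_responses(responses, thr)

  go_types <- sort(unique(trials$trial_type[trials$trial_type > 0]))
  metric_rows <- list(); matched_rows <- list()
  for (tt in go_types) {
    zones <- session$targets[session$targets$trial_type == tt,
                             c("x_um", "y_um", "z_um")]
    labels <- classify_rois(tr$centroids_um, zones, radius_um = radius_um)
    t_idx <- which(trials$trial_type == tt & trials$outcome != "excluded")
    if (length(t_idx) == 0L) next
    props <- network_proportions(cls, labels, t_idx)
    counts <- colSums(cls[labels, t_idx, drop = FALSE] == "activated")
    per_trial <- data.frame(
      n_targets_activated = counts,
      p_activated_all = props$p_activated_all,
      p_suppressed_all = props$p_suppressed_all,
      p_activated_bg = props$p_activated_bg,
      p_suppressed_bg = props$p_suppressed_bg)
    metric_rows[[as.character(tt)]] <- data.frame(
      trial_type = tt, n_trials = length(t_idx),
      t(colMeans(per_trial)))
    m <- match_hit_miss(as.character(trials$outcome[t_idx]), per_trial,
                        n_perm = n_perm_match, seed = derive_seed(seed, tt))
    matched_rows[[as.character(tt)]] <- cbind(
      data.frame(trial_type = tt, n_minority = m$n_minority,
                 excluded = m$excluded),
      as.data.frame(as.list(m$means)))
  }

  list(trials = trials, responses = responses, thresholds = thr,
       classification = cls,
       sf_activation = cal_act$scaling_factor,
       sf_suppression = cal_sup$scaling_factor,
       calibration = list(activation = cal_act, suppression = cal_sup),
       neuropil_coeff = coefs,
       type_metrics = do.call(rbind, metric_rows),
       matched = do.call(rbind, matched_rows),
       behavior = behavior_summary(trials))
}

#' Suppression/activation trend versus activated targets
#'
#' Convenience wrapper for the network-trend analyses: takes the matched
#' (or raw) per-type metric table(s) from one or more sessions, drops
#' trial types whose mean activated-target count is below 1, and fits the
#' OLS trend of a chosen proportion against the mean number of activated
#' targets.
#'
#' @param metric_table data.frame with columns `n_targets_activated` and
#'   the chosen metric (rows = trial type x session datapoints).
#' @param metric column name to regress.
#' @return a [linear_trend()] fit.
#' @export
network_trend <- function(metric_table, metric = "p_suppressed_bg") {
  keep <- eligible_trial_types(metric_table$n_targets_activated)
  if ("excluded" %in% names(metric_table)) keep <- keep & !metric_table$excluded
  tab <- metric_table[keep, , drop = FALSE]
  linear_trend(tab$n_targets_activated, tab[[metric]])
}
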