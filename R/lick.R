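#' Smooth a lick raster into a continuous rate trace
#'
#' Sum of unit-mass Gaussian kernels (default sigma 0.5 s) centred at each
#' lick time, evaluated on the imaging timebase. The integral of the trace
#' approximates the number of licks (boundary effects aside).
#'
#' @param lick_times_s lick times.
#' @param timebase_s sample times at which to evaluate the trace.
#' @param sigma_s Gaussian kernel SD.
#' @return numeric trace, same length as `timebase_s`.
#' @export
smooth_licks <- function(lick_times_s, timebase_s, sigma_s = 0.5) {
  out <- numeric(length(timebase_s))
  for (lt in lick_times_s) {
    out <- out + stats::dnorm(timebase_s, mean = lt, sd = sigma_s)
  }
  out
}

#' Lick-modulation of fluorescence by Pearson correlation
#'
#' Correlates each neuron's fluorescence trace with the smoothed lick
#' trace over spontaneous (non-trial) periods: samples within 0--4 s after
#' any stimulus onset are removed, and the analysis span runs from the
#' first to the last spontaneous lick. A neuron is "lick modulated" when
#' the two-sided p-value falls below `alpha`; the sign of modulation is the
#' sign of r.
#'
#' @param f_cell neurons x samples fluorescence matrix.
#' @param lick_trace smoothed lick trace (length = samples).
#' @param timebase_s sample times.
#' @param trial_onsets_s stimulus onset times whose post-stimulus periods
#'   are excised.
#' @param exclusion_window_s seconds after each onset to remove.
#' @param span_s optional `c(first, last)` spontaneous-lick span; computed
#'   from `spont_lick_times_s` when given, otherwise the full timebase.
#' @param spont_lick_times_s spontaneous lick times used to derive the span.
#' @param alpha two-sided significance threshold for "modulated".
#' @param min_samples minimum retained samples.
#' @return data.frame per neuron: `r`, `p`, `modulated`, `sign`; attribute
#'   `fraction_modulated`.
#' @export
lick_correlation <- function(f_cell, lick_trace, timebase_s, trial_onsets_s,
                             exclusion_window_s = c(0, 4), span_s = NULL,
                             spont_lick_times_s = NULL, alpha = 0.05,
                             min_samples = 30L) {
  abort_if(!is.matrix(f_cell) || ncol(f_cell) != length(timebase_s),
           "lick_correlation(): f_cell must be neurons x samples")
  keep <- rep(TRUE, length(timebase_s))
  for (on in trial_onsets_s) {
    keep[timebase_s >= on + exclusion_window_s[1] &
           timebase_s <= on + exclusion_window_s[2]] <- FALSE
  }
  if (is.null(span_s) && !is.null(spont_lick_times_s) &&
      length(spont_lick_times_s) > 0L) {
    span_s <- range(spont_lick_times_s)
  }
  if (!is.null(span_s)) {
    keep[timebase_s < span_s[1] | timebase_s > span_s[2]] <- FALSE
  }
  abort_if(sum(keep) < min_samples,
           "lick_correlation(): fewer retained samples than min_samples")
  lt <- lick_trace[keep]
  res <- t(vapply(seq_len(nrow(f_cell)), function(i) {
    y <- f_cell[i, keep]
    if (stats::sd(y) == 0 || stats::sd(lt) == 0) return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(y, lt, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  mod <- !is.na(res[, 2]) & res[, 2] < alpha
  out <- data.frame(neuron = seq_len(nrow(f_cell)), r = res[, 1], p = res[, 2],
                    modulated = mod,
                    sign = ifelse(is.na(res[, 1]), NA_character_,
                                  ifelse(res[, 1] >= 0, "positive", "negative")))
  attr(out, "fraction_modulated") <- mean(mod)
  out
}

#' Detect spontaneous lick bouts
#'
#' A bout is a maximal run of at least `min_licks` licks whose consecutive
#' inter-lick intervals are all at most `within_bout_ili_s`, whose first
#' lick is separated from any preceding lick by at least `pre_quiet_s`, and
#' whose onset lies outside masked trial periods (default 0--4 s after any
#' stimulus onset).
#'
#' @param lick_times_s sorted lick times.
#' @param min_licks minimum licks per bout.
#' @param within_bout_ili_s maximum interval between successive bout licks.
#' @param pre_quiet_s required lick-free period before bout onset.
#' @param trial_onsets_s stimulus onsets defining masked periods (optional).
#' @param mask_window_s masked window after each onset.
#' @return numeric vector of bout onset times.
#' @export
detect_lick_bouts <- function(lick_times_s, min_licks = 3L,
                              within_bout_ili_s = 0.5, pre_quiet_s = 1,
                              trial_onsets_s = numeric(),
                              mask_window_s = c(0, 4)) {
  abort_if(is.unsorted(lick_times_s), "detect_lick_bouts(): lick times must be sorted")
  n <- length(lick_times_s)
  if (n < min_licks) return(numeric())
  gaps <- diff(lick_times_s)
  # split into maximal runs of close licks
  run_id <- cumsum(c(0, gaps > within_bout_ili_s))
  onsets <- numeric()
  for (id in unique(run_id)) {
    idx <- which(run_id == id)
    if (length(idx) < min_licks) next
    first <- lick_times_s[idx[1]]
    if (idx[1] > 1L && first - lick_times_s[idx[1] - 1L] < pre_quiet_s) next
    in_trial <- any(first >= trial_onsets_s + mask_window_s[1] &
                      first <= trial_onsets_s + mask_window_s[2])
    if (in_trial) next
    onsets <- c(onsets, first)
  }
  onsets
}
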