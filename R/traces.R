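#' Estimate the neuropil-subtraction coefficient for one ROI
#'
#' Robust linear regression (iteratively reweighted least squares with a
#' bisquare weight) of the ROI trace on its neuropil trace, after removing
#' photostimulation epochs and block-averaging the remaining samples by a
#' factor of 10. The slope is bounded post hoc to \[0.5, 1\]. An estimate is
#' "unreliable" (returns `NA`) when the regression does not converge, the
#' slope is non-finite, or fewer than `min_points` masked-downsampled points
#' remain; session-level code substitutes the median of reliable estimates
#' (see [fill_unreliable_coefficients()]).
#'
#' @param f_roi,f_neuropil equal-length numeric traces for one ROI.
#' @param exclude_mask logical vector (`TRUE` = excluded sample), or `NULL`.
#' @param downsample block size for downsampling (block means).
#' @param bounds slope bounds applied after estimation.
#' @param min_points minimum usable downsampled points.
#' @return the bounded coefficient, or `NA_real_` if unreliable.
#' @export
estimate_neuropil_coefficient <- function(f_roi, f_neuropil, exclude_mask = NULL,
                                          downsample = 10L, bounds = c(0.5, 1),
                                          min_points = 20L) {
  abort_if(length(f_roi) != length(f_neuropil),
           "estimate_neuropil_coefficient(): trace lengths differ")
  keep <- if (is.null(exclude_mask)) rep(TRUE, length(f_roi)) else !exclude_mask
  y <- f_roi[keep]; x <- f_neuropil[keep]
  if (length(y) == 0L) return(NA_real_)
  y <- block_means(y, downsample)
  x <- block_means(x, downsample)
  if (length(x) < min_points || stats::sd(x) == 0) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 50)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NA_real_)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope)) return(NA_real_)
  min(max(slope, bounds[1]), bounds[2])
}

block_means <- function(v, k) {
  if (k <= 1L) return(v)
  n <- floor(length(v) / k)
  if (n == 0L) return(numeric())
  colMeans(matrix(v[seq_len(n * k)], nrow = k))
}

#' Replace unreliable neuropil coefficients with the session median
#'
#' @param coefs per-neuron coefficients with `NA` for unreliable estimates.
#' @return coefficients with `NA`s replaced by the median of the rest.
#' @export
fill_unreliable_coefficients <- function(coefs) {
  bad <- is.na(coefs)
  if (all(bad)) stop("fill_unreliable_coefficients(): no reliable estimates",
                     call. = FALSE)
  coefs[bad] <- stats::median(coefs[!bad])
  coefs
}

#' Neuropil subtraction with re-baselining
#'
#' `F_cell = F_ROI - c * F_neuropil`, then offset so that the 33rd
#' percentile of `F_cell` equals the 33rd percentile of `F_ROI` (keeping
#' subsequent dF/F and dF/sigmaF computations on the raw-trace baseline
#' scale).
#'
#' @param f_roi,f_neuropil traces (vectors, or neurons x time matrices with
#'   a shared or per-neuron `c`).
#' @param c neuropil coefficient(s) in \[0, 1\].
#' @return the corrected, re-baselined trace(s).
#' @export
subtract_and_rebaseline <- function(f_roi, f_neuropil, c) {
  abort_if(any(c < 0 | c > 1), "subtract_and_rebaseline(): c must be in [0, 1]")
  if (is.matrix(f_roi)) {
    abort_if(!is.matrix(f_neuropil) || !all(dim(f_roi) == dim(f_neuropil)),
             "subtract_and_rebaseline(): dimension mismatch")
    cc <- rep_len(c, nrow(f_roi))
    out <- f_roi - cc * f_neuropil
    for (i in seq_len(nrow(out))) {
      out[i, ] <- out[i, ] - stats::quantile(out[i, ], 0.33, names = FALSE) +
        stats::quantile(f_roi[i, ], 0.33, names = FALSE)
    }
    return(out)
  }
  f_cell <- f_roi - c * f_neuropil
  f_cell - stats::quantile(f_cell, 0.33, names = FALSE) +
    stats::quantile(f_roi, 0.33, names = FALSE)
}

#' Photostimulation artefact-exclusion mask
#'
#' Imaging volumes corrupted by the photostimulus are excluded identically
#' on every trial so that all trial types lose the same amount of data:
#' the volume whose acquisition interval contains stimulus onset, the
#' volume immediately before it (the stimulus can begin during its last
#' plane), and the three following volumes -- five consecutive volumes
#' (about 750 ms at a 6.69 Hz volume rate).
#'
#' @param trial_onsets_s stimulus onset times.
#' @param volume_times_s strictly increasing volume acquisition times.
#' @param n_before,n_after volumes excluded either side of the onset volume.
#' @return integer matrix, one row per trial, of excluded volume indices
#'   (clipped to the recorded range; the count before clipping is always
#'   `n_before + 1 + n_after`).
#' @export
artefact_exclusion_mask <- function(trial_onsets_s, volume_times_s,
                                    n_before = 1L, n_after = 3L) {
  abort_if(is.unsorted(volume_times_s, strictly = TRUE),
           "artefact_exclusion_mask(): volume times must be strictly increasing")
  if (length(trial_onsets_s) == 0L) {
    return(matrix(integer(), nrow = 0, ncol = n_before + 1L + n_after))
  }
  abort_if(any(trial_onsets_s < volume_times_s[1] |
                 trial_onsets_s > volume_times_s[length(volume_times_s)]),
           "artefact_exclusion_mask(): trial onset outside recorded span")
  onset_vol <- findInterval(trial_onsets_s, volume_times_s)
  idx <- vapply(onset_vol, function(v) (v - n_before):(v + n_after),
                integer(n_before + 1L + n_after))
  t(idx)
}

#' Trial-wise dF/sigmaF responses
#'
#' For each neuron and trial, the stimulus-triggered trace is converted to
#' dF/sigmaF by subtracting the mean and dividing by the SD of a 1 s
#' pre-onset baseline, and the response is the average over unmasked
#' volumes whose time falls in the post-onset response window (default
#' 0.7--1.0 s, past the artefact-exclusion epoch). Catch trials are aligned
#' to their response-window onset time exactly like go trials. A neuron
#' with zero baseline SD on a trial yields `NA` (propagated, never zero).
#'
#' @param f_cell neurons x volumes matrix of corrected traces.
#' @param volume_times_s volume acquisition times.
#' @param trial_onsets_s per-trial alignment times.
#' @param exclusion volume-index matrix from [artefact_exclusion_mask()],
#'   or `NULL` for no exclusion.
#' @param baseline_s baseline duration before onset.
#' @param response_window_s post-onset window `c(lo, hi)` (volume times in
#'   `[lo, hi]` are averaged).
#' @return neurons x trials matrix of dF/sigmaF responses.
#' @export
extract_trial_responses <- function(f_cell, volume_times_s, trial_onsets_s,
                                    exclusion = NULL, baseline_s = 1,
                                    response_window_s = c(0.7, 1.0)) {
  abort_if(!is.matrix(f_cell) || ncol(f_cell) != length(volume_times_s),
           "extract_trial_responses(): f_cell must be neurons x volumes")
  n_trials <- length(trial_onsets_s)
  out <- matrix(NA_real_, nrow = nrow(f_cell), ncol = n_trials)
  for (j in seq_len(n_trials)) {
    on <- trial_onsets_s[j]
    excl <- if (is.null(exclusion)) integer() else exclusion[j, ]
    rel <- volume_times_s - on
    base_idx <- setdiff(which(rel >= -baseline_s & rel < 0), excl)
    resp_idx <- setdiff(which(rel >= response_window_s[1] &
                                rel <= response_window_s[2]), excl)
    abort_if(length(base_idx) < 2L,
             sprintf("extract_trial_responses(): trial %d has < 2 baseline volumes", j))
    abort_if(length(resp_idx) < 1L,
             sprintf("extract_trial_responses(): trial %d has no response volumes", j))
    bmean <- rowMeans(f_cell[, base_idx, drop = FALSE])
    bsd <- row_sds(f_cell[, base_idx, drop = FALSE])
    rmean <- rowMeans(f_cell[, resp_idx, drop = FALSE])
    r <- (rmean - bmean) / bsd
    r[bsd == 0] <- NA_real_
    out[, j] <- r
  }
  out
}
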