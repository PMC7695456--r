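#' Per-neuron activation/suppression thresholds from catch-trial responses
#'
#' Each neuron's response distribution on correct-reject (CR) catch trials
#' (no stimulus, no lick) defines its thresholds:
#' \deqn{thr_{act} = mean_{catch} + SD_{catch} \times SF_{act}, \quad
#'       thr_{sup} = mean_{catch} - SD_{catch} \times SF_{sup}}
#' with one session-wide scaling factor per response kind (see
#' [calibrate_scaling_factor()]).
#'
#' @param cr_catch_responses neurons x CR-catch-trials matrix of dF/sigmaF
#'   responses.
#' @param sf_activation,sf_suppression session scaling factors.
#' @return object of class `threshold_set`: list with per-neuron
#'   `mean_catch`, `sd_catch`, `thr_activation`, `thr_suppression` and the
#'   scalars `sf_activation`, `sf_suppression`.
#' @export
compute_thresholds <- function(cr_catch_responses, sf_activation, sf_suppression) {
  abort_if(!is.matrix(cr_catch_responses) || ncol(cr_catch_responses) < 2L,
           "compute_thresholds(): need >= 2 CR catch trials per neuron")
  m <- rowMeans(cr_catch_responses)
  s <- row_sds(cr_catch_responses)
  structure(list(
    mean_catch = m, sd_catch = s,
    sf_activation = sf_activation, sf_suppression = sf_suppression,
    thr_activation = m + s * sf_activation,
    thr_suppression = m - s * sf_suppression
  ), class = "threshold_set")
}

#' Calibrate a session's SD scaling factor to a fixed false-positive rate
#'
#' Sweeps candidate scaling factors (default 1 to 3 in steps of 0.1). At
#' each value, permuted 80:20 train:test splits over CR catch trials define
#' thresholds on the training trials and measure, on each held-out test
#' trial, the proportion of neurons crossing; this proportion is averaged
#' over test trials and the median over permutations gives one point of the
#' calibration curve. The curve is interpolated with a cubic spline
#' (falling back to a monotone piecewise-cubic when the plain cubic is
#' non-monotone over the sweep) and inverted at the target false-positive
#' rate (default 5\%). Activation and suppression are calibrated
#' independently; the returned factor is clipped to the sweep range with a
#' warning when the target is unattainable inside it.
#'
#' @param cr_catch_responses neurons x CR-catch-trials matrix.
#' @param response_kind `"activation"` (crossing above) or `"suppression"`
#'   (crossing below).
#' @param sweep candidate scaling factors (increasing).
#' @param n_perm number of permuted train:test splits.
#' @param train_frac training fraction of each split.
#' @param target_fp target held-out false-positive rate.
#' @param seed RNG seed for the splits.
#' @return object of class `calibration` with `scaling_factor`, the sweep
#'   `curve` (data.frame: sf, median_fp), `response_kind`, `target_fp`.
#' @export
calibrate_scaling_factor <- function(cr_catch_responses,
                                     response_kind = c("activation", "suppression"),
                                     sweep = seq(1, 3, by = 0.1),
                                     n_perm = 10000, train_frac = 0.8,
                                     target_fp = 0.05, seed = NULL) {
  response_kind <- match.arg(response_kind)
  abort_if(!is.matrix(cr_catch_responses),
           "calibrate_scaling_factor(): responses must be a matrix")
  n_trials <- ncol(cr_catch_responses)
  n_train <- floor(train_frac * n_trials)
  abort_if(n_train < 2L || n_trials - n_train < 1L,
           "calibrate_scaling_factor(): too few CR catch trials for the split")
  abort_if(is.unsorted(sweep, strictly = TRUE),
           "calibrate_scaling_factor(): sweep must be increasing")

  # One pass per permutation: per-neuron train mean/SD, then the held-out
  # z-scores; FP(sf) = mean(z > sf) follows for every sweep value at once.
  fp <- local_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      tr <- sample.int(n_trials, n_train)
      te <- setdiff(seq_len(n_trials), tr)
      x <- cr_catch_responses[, tr, drop = FALSE]
      m <- rowMeans(x)
      s <- row_sds(x)
      z <- (cr_catch_responses[, te, drop = FALSE] - m) / s
      if (response_kind == "suppression") z <- -z
      z <- z[is.finite(z)]
      if (length(z) == 0L) return(rep(NA_real_, length(sweep)))
      zs <- sort(z)
      # proportion of held-out neuron-trials strictly above each sweep value
      1 - findInterval(sweep, zs, left.open = FALSE) / length(zs)
    }, numeric(length(sweep)))
  })
  median_fp <- apply(fp, 1L, stats::median, na.rm = TRUE)
  sf <- invert_calibration_curve(sweep, median_fp, target_fp)
  structure(list(
    scaling_factor = sf, response_kind = response_kind, target_fp = target_fp,
    curve = data.frame(sf = sweep, median_fp = median_fp),
    n_perm = n_perm, train_frac = train_frac
  ), class = "calibration")
}

# Cubic interpolation of the (decreasing) median-FP curve, inverted at the
# target rate. Falls back to a monotone piecewise cubic (on the isotonic
# projection of the curve) when the natural cubic is non-monotone.
invert_calibration_curve <- function(sweep, median_fp, target_fp) {
  f <- stats::splinefun(sweep, median_fp, method = "natural")
  grid <- seq(min(sweep), max(sweep), length.out = 2001)
  vals <- f(grid)
  if (any(diff(vals) > 1e-12)) {
    # isotonic (decreasing) projection, then monotone Hermite cubic
    iso <- -stats::isoreg(sweep, -median_fp)$yf
    f <- stats::splinefun(sweep, iso, method = "monoH.FC")
    vals <- f(grid)
  }
  if (target_fp >= vals[1]) {
    warning("calibration: target FP at or above the curve; returning sweep minimum",
            call. = FALSE)
    return(min(sweep))
  }
  if (target_fp <= vals[length(vals)]) {
    warning("calibration: target FP at or below the curve; returning sweep maximum",
            call. = FALSE)
    return(max(sweep))
  }
  stats::uniroot(function(s) f(s) - target_fp, range(sweep), tol = 1e-8)$root
}

#' Classify trial-wise responses against thresholds
#'
#' Trinary classification per neuron per trial: `activated` when the
#' response is strictly above the activation threshold, `suppressed` when
#' strictly below the suppression threshold, otherwise `none`. A response
#' exactly at a threshold is `none` (thresholds must be *crossed*).
#' Undefined (`NA`) responses classify as `none` and are flagged in the
#' `"undefined"` attribute.
#'
#' @param responses neurons x trials response matrix.
#' @param thresholds a `threshold_set` from [compute_thresholds()].
#' @return character matrix (same shape) with values `"activated"`,
#'   `"suppressed"`, `"none"`; attribute `undefined` marks NA responses.
#' @export
classify_responses <- function(responses, thresholds) {
  abort_if(!is.matrix(responses) ||
             nrow(responses) != length(thresholds$thr_activation),
           "classify_responses(): shape mismatch between responses and thresholds")
  cls <- matrix("none", nrow = nrow(responses), ncol = ncol(responses))
  act <- responses > thresholds$thr_activation
  sup <- responses < thresholds$thr_suppression
  cls[which(act)] <- "activated"
  cls[which(sup & !act)] <- "suppressed"
  und <- is.na(responses)
  cls[which(und)] <- "none"
  attr(cls, "undefined") <- und
  cls
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("%s scaling factor calibration (target FP %.1f%%)\n",
              x$response_kind, 100 * x$target_fp))
  cat(sprintf("  scaling factor = %.3f (%d permutations, sweep %.1f-%.1f)\n",
              x$scaling_factor, x$n_perm, min(x$curve$sf), max(x$curve$sf)))
  invisible(x)
}
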