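#' Classify ROIs as target or background for one trial type
#'
#' Photostimulation target zones are conservative 3D cylinders: a 10 um
#' lateral radius (about twice the lateral resolution of two-photon
#' photostimulation) extending through the entire axial range of the
#' imaging volume. An ROI is a potential target when its centroid lies
#' laterally within (<=) the radius of any target location of that trial
#' type, irrespective of axial displacement; all other ROIs are background.
#'
#' @param roi_centroids_um ROIs x 3 matrix of (x, y, z) centroids in um.
#' @param zone_coords_um zones x 2 or zones x 3 matrix of target (x, y\[, z\])
#'   coordinates for one trial type.
#' @param radius_um lateral zone radius.
#' @return logical vector: `TRUE` = target, `FALSE` = background.
#' @export
classify_rois <- function(roi_centroids_um, zone_coords_um, radius_um = 10) {
  abort_if(is.null(zone_coords_um) || NROW(zone_coords_um) == 0L,
           "classify_rois(): empty target-zone list for a go trial type")
  abort_if(radius_um <= 0, "classify_rois(): radius must be > 0")
  rc <- as.matrix(roi_centroids_um)[, 1:2, drop = FALSE]
  zc <- as.matrix(zone_coords_um)[, 1:2, drop = FALSE]
  # squared lateral distance ROI x zone
  d2 <- outer(rc[, 1], zc[, 1], "-")^2 + outer(rc[, 2], zc[, 2], "-")^2
  apply(d2 <= radius_um^2, 1L, any)
}

#' Mean number of activated target neurons for a trial type
#'
#' Counts, on each trial of the type, the target-labelled neurons that
#' crossed their activation threshold, and averages across trials.
#'
#' @param class_matrix neurons x trials classification
#'   (see [classify_responses()]).
#' @param target_labels logical per-neuron target flag for this trial type.
#' @param trial_idx column indices of the trials of this type.
#' @return mean activated-target count (scalar).
#' @export
count_activated_targets <- function(class_matrix, target_labels, trial_idx) {
  if (length(trial_idx) == 0L) return(NA_real_)
  sub <- class_matrix[target_labels, trial_idx, drop = FALSE]
  mean(colSums(sub == "activated"))
}

#' Per-trial network activation/suppression proportions
#'
#' For each trial: the proportion of all imaged neurons activated or
#' suppressed (numerator over all neurons), and the background-only
#' variants where target-labelled neurons are excluded from the numerator
#' but the denominator remains the total number of neurons (targets and
#' background), keeping proportions comparable across trial types.
#'
#' @param class_matrix neurons x trials classification.
#' @param target_labels logical per-neuron target flag.
#' @param trial_idx optional column subset (default all columns).
#' @return data.frame with one row per trial: `p_activated_all`,
#'   `p_suppressed_all`, `p_activated_bg`, `p_suppressed_bg`,
#'   `act_sup_ratio` (NA when the trial has no suppressed neurons).
#' @export
network_proportions <- function(class_matrix, target_labels,
                                trial_idx = seq_len(ncol(class_matrix))) {
  n_neurons <- nrow(class_matrix)
  sub <- class_matrix[, trial_idx, drop = FALSE]
  bg <- sub[!target_labels, , drop = FALSE]
  act_all <- colSums(sub == "activated") / n_neurons
  sup_all <- colSums(sub == "suppressed") / n_neurons
  act_bg <- colSums(bg == "activated") / n_neurons
  sup_bg <- colSums(bg == "suppressed") / n_neurons
  ratio <- ifelse(sup_all > 0, act_all / sup_all, NA_real_)
  data.frame(trial = trial_idx, p_activated_all = act_all,
             p_suppressed_all = sup_all, p_activated_bg = act_bg,
             p_suppressed_bg = sup_bg, act_sup_ratio = ratio)
}

#' Ordinary least-squares trend with confidence interval
#'
#' Linear fit of a network metric against the mean number of activated
#' targets (one datapoint per trial type per session), reporting the slope
#' with its 95\% confidence interval, R-squared, and the two-sided p-value
#' for slope = 0.
#'
#' @param x predictor values (e.g. mean activated targets per datapoint).
#' @param y response values (e.g. P(suppressed)).
#' @param conf confidence level for the slope interval.
#' @return list with `beta`, `ci` (length 2), `intercept`, `r2`, `p`, `n`.
#' @export
linear_trend <- function(x, y, conf = 0.95) {
  abort_if(length(x) != length(y), "linear_trend(): x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  abort_if(length(x) < 3L, "linear_trend(): need >= 3 datapoints")
  abort_if(stats::sd(x) == 0, "linear_trend(): constant predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = conf)
  list(beta = unname(stats::coef(fit)["x"]),
       ci = as.numeric(ci),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r2 = sm$r.squared,
       p = sm$coefficients["x", "Pr(>|t|)"],
       n = length(x))
}

#' Trial types eligible for trend analyses
#'
#' Trial types whose mean activated-target count is below 1 carry
#' essentially no effective stimulus and are excluded from trend analyses.
#'
#' @param mean_activated_targets named vector, one value per trial type.
#' @param min_mean minimum mean activated-target count.
#' @return logical eligibility vector.
#' @export
eligible_trial_types <- function(mean_activated_targets, min_mean = 1) {
  mean_activated_targets >= min_mean
}
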