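#' Hit:miss matched network metrics
#'
#' Licking itself drives network activity, and easy stimuli are mostly hits
#' while hard stimuli are mostly misses, so raw per-type averages of
#' network metrics confound stimulus size with lick contamination. This
#' procedure fixes a 50:50 hit:miss ratio on every trial type: over
#' `n_perm` permutations it takes *all* trials of the minority response
#' class plus an equal-sized random resample (without replacement) of the
#' majority class, averages each metric over the selected trials, and then
#' averages over permutations. Trial types with only one response class
#' present are excluded.
#'
#' @param outcomes character/factor per trial: `"hit"` or `"miss"`
#'   (anything else is ignored).
#' @param metrics data.frame or matrix of per-trial metric values (rows =
#'   trials, aligned with `outcomes`).
#' @param n_perm number of permutations.
#' @param seed RNG seed; each permutation derives its own sub-stream so the
#'   selected trials do not depend on which metrics are attached.
#' @param details if `TRUE`, attach the per-permutation selections.
#' @return object of class `matched_metrics`: list with `means` (named
#'   metric means), `n_minority`, `n_perm`, `excluded`, `reason`, and (with
#'   `details`) `permutations` (list of index vectors) and `hit_fraction`
#'   (per-permutation fraction of hits among selected trials).
#' @export
match_hit_miss <- function(outcomes, metrics, n_perm = 100, seed = NULL,
                           details = FALSE) {
  outcomes <- as.character(outcomes)
  metrics <- as.data.frame(metrics)
  abort_if(nrow(metrics) != length(outcomes),
           "match_hit_miss(): metrics rows must match outcomes length")
  hits <- which(outcomes == "hit")
  misses <- which(outcomes == "miss")
  if (length(hits) == 0L || length(misses) == 0L) {
    return(structure(list(
      means = stats::setNames(rep(NA_real_, ncol(metrics)), names(metrics)),
      n_minority = min(length(hits), length(misses)), n_perm = n_perm,
      excluded = TRUE, reason = "single_response_class"
    ), class = "matched_metrics"))
  }
  if (length(hits) <= length(misses)) {
    minority <- hits; majority <- misses
  } else {
    minority <- misses; majority <- hits
  }
  n_min <- length(minority)

  perms <- lapply(seq_len(n_perm), function(p) {
    samp <- local_seed(if (is.null(seed)) NULL else derive_seed(seed, p), {
      sample(majority, n_min, replace = FALSE)
    })
    sort(c(minority, samp))
  })
  per_perm_means <- vapply(perms, function(idx) {
    colMeans(as.matrix(metrics[idx, , drop = FALSE]))
  }, numeric(ncol(metrics)))
  if (ncol(metrics) == 1L) per_perm_means <- matrix(per_perm_means, nrow = 1L)
  means <- stats::setNames(rowMeans(per_perm_means), names(metrics))

  out <- structure(list(
    means = means, n_minority = n_min, n_perm = n_perm,
    excluded = FALSE, reason = NA_character_
  ), class = "matched_metrics")
  if (details) {
    out$permutations <- perms
    out$hit_fraction <- vapply(perms, function(idx) {
      mean(outcomes[idx] == "hit")
    }, numeric(1))
  }
  out
}

#' Hit:miss matched metrics for every trial type
#'
#' Applies [match_hit_miss()] separately within each trial type.
#'
#' @param trial_types per-trial type labels.
#' @param outcomes per-trial `"hit"`/`"miss"` outcomes.
#' @param metrics per-trial metric data.frame.
#' @param n_perm,seed see [match_hit_miss()].
#' @return data.frame, one row per trial type, with matched metric means,
#'   `n_minority` and `excluded` columns.
#' @export
match_hit_miss_by_type <- function(trial_types, outcomes, metrics,
                                   n_perm = 100, seed = NULL) {
  types <- sort(unique(trial_types))
  rows <- lapply(types, function(tt) {
    sel <- trial_types == tt
    m <- match_hit_miss(outcomes[sel], metrics[sel, , drop = FALSE],
                        n_perm = n_perm,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, tt))
    cbind(data.frame(trial_type = tt, n_minority = m$n_minority,
                     excluded = m$excluded),
          as.data.frame(as.list(m$means)))
  })
  do.call(rbind, rows)
}
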