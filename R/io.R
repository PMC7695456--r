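#' Write a session bundle to a directory
#'
#' Persists a session as portable plain-text files: `trials.csv` (lick
#' times semicolon-joined), `targets.csv`, `centroids.csv`,
#' `volume_times.csv`, the trace matrices `f_roi.csv` / `f_neuropil.csv`
#' (neurons x volumes, no headers), and `ground_truth.json`. Traces are
#' plain CSV rather than a binary array container so bundles remain
#' inspectable and diff-able; real datasets at full scale would use HDF5.
#'
#' @param session a `sim_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trials
  trials_out <- data.frame(
    trial_index = tr$trial_index,
    trial_type = tr$trial_type,
    onset_s = tr$onset_s,
    lick_times_s = vapply(tr$lick_times_s, function(v)
      paste(signif(v, 10), collapse = ";"), character(1)),
    autoreward_s = if ("autoreward_s" %in% names(tr)) tr$autoreward_s else NA_real_,
    warmup = if ("warmup" %in% names(tr)) tr$warmup else FALSE)
  utils::write.csv(trials_out, file.path(dir, "trials.csv"), row.names = FALSE)
  if (!is.null(session$targets)) {
    utils::write.csv(session$targets, file.path(dir, "targets.csv"),
                     row.names = FALSE)
  }
  if (!is.null(session$traces)) {
    tt <- session$traces
    utils::write.csv(as.data.frame(tt$centroids_um),
                     file.path(dir, "centroids.csv"), row.names = FALSE)
    utils::write.csv(data.frame(volume_times_s = tt$volume_times_s),
                     file.path(dir, "volume_times.csv"), row.names = FALSE)
    utils::write.table(tt$f_roi, file.path(dir, "f_roi.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(tt$f_neuropil, file.path(dir, "f_neuropil.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth
    gt$suppression_events <- NULL  # large; reconstructable from the seed
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Inverse of [write_session_bundle()]; components that were not written
#' (e.g. traces) are `NULL`.
#'
#' @param dir bundle directory.
#' @return a `sim_session`-shaped list.
#' @export
read_session_bundle <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  trials$lick_times_s <- parse_lick_column(trials$lick_times_s)
  targets <- NULL
  tfile <- file.path(dir, "targets.csv")
  if (file.exists(tfile)) targets <- utils::read.csv(tfile)
  traces <- NULL
  if (file.exists(file.path(dir, "f_roi.csv"))) {
    traces <- list(
      f_roi = as.matrix(utils::read.csv(file.path(dir, "f_roi.csv"),
                                        header = FALSE)),
      f_neuropil = as.matrix(utils::read.csv(file.path(dir, "f_neuropil.csv"),
                                             header = FALSE)),
      volume_times_s = utils::read.csv(file.path(dir, "volume_times.csv"))$volume_times_s,
      centroids_um = as.matrix(utils::read.csv(file.path(dir, "centroids.csv"))))
    dimnames(traces$f_roi) <- NULL
    dimnames(traces$f_neuropil) <- NULL
  }
  gt <- NULL
  gfile <- file.path(dir, "ground_truth.json")
  if (file.exists(gfile)) gt <- jsonlite::read_json(gfile, simplifyVector = TRUE)
  structure(list(trials = trials, targets = targets, traces = traces,
                 ground_truth = gt), class = "sim_session")
}
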