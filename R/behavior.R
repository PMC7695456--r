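#' Score go/catch trials from lick times
#'
#' Assigns each trial an outcome and reaction time from its lick raster.
#' The response window opens 0.15 s after stimulus onset (licks at or before
#' 0.15 s are deemed too fast to be stimulus-driven and the trial is
#' excluded) and extends 1 s, i.e. 0.15--1.15 s post onset. Go trials with a
#' first in-window lick are hits, otherwise misses; catch trials become
#' false alarms or correct rejects. Auto-rewarded trials are scored
#' conservatively: a hit only if the animal licked before
#' `autoreward_s + 0.15`, otherwise a miss even if a later lick falls inside
#' the response window.
#'
#' @param trials data.frame with columns `trial_index`, `trial_type`
#'   (integer target-zone count, 0 = catch), `onset_s`, `lick_times_s`
#'   (list-column of numeric vectors, or semicolon-joined strings), and
#'   optionally `autoreward_s` (NA when absent).
#' @param response_window numeric length-2: window (s, post onset) in which
#'   a first lick counts as a response.
#' @return the trial data.frame with `outcome` (factor: hit, miss,
#'   false_alarm, correct_reject, excluded), `reaction_time_s` and
#'   `exclusion_reason` columns.
#' @export
score_trials <- function(trials, response_window = c(0.15, 1.15)) {
  stopifnot(is.data.frame(trials))
  need <- c("trial_index", "trial_type", "onset_s", "lick_times_s")
  abort_if(!all(need %in% names(trials)),
           paste("score_trials(): trials must have columns",
                 paste(need, collapse = ", ")))
  licks <- parse_lick_column(trials$lick_times_s)
  auto <- if ("autoreward_s" %in% names(trials)) trials$autoreward_s else
    rep(NA_real_, nrow(trials))

  outcome <- character(nrow(trials))
  rt <- rep(NA_real_, nrow(trials))
  reason <- rep(NA_character_, nrow(trials))

  for (i in seq_len(nrow(trials))) {
    lk <- licks[[i]]
    abort_if(any(lk < 0), "score_trials(): negative lick times")
    abort_if(is.unsorted(lk), "score_trials(): lick times must be sorted")
    rel <- lk - trials$onset_s[i]
    rel <- rel[rel > 0]
    first <- if (length(rel)) rel[1] else NA_real_
    is_go <- trials$trial_type[i] > 0

    if (!is.na(first) && first <= response_window[1]) {
      outcome[i] <- "excluded"
      reason[i] <- "rt_too_fast"
      next
    }
    if (!is.na(auto[i]) && is_go) {
      # auto-rewarded trial: hit only if lick precedes reward + grace
      if (!is.na(first) && first < auto[i] + response_window[1]) {
        outcome[i] <- "hit"; rt[i] <- first
      } else outcome[i] <- "miss"
      next
    }
    responded <- !is.na(first) && first > response_window[1] &&
      first <= response_window[2]
    if (is_go) {
      if (responded) { outcome[i] <- "hit"; rt[i] <- first }
      else outcome[i] <- "miss"
    } else {
      if (responded) { outcome[i] <- "false_alarm"; rt[i] <- first }
      else outcome[i] <- "correct_reject"
    }
  }
  trials$outcome <- factor(outcome, levels = c("hit", "miss", "false_alarm",
                                               "correct_reject", "excluded"))
  trials$reaction_time_s <- rt
  trials$exclusion_reason <- reason
  trials$lick_times_s <- licks
  trials
}

# Accept either a list-column of numeric vectors or ";"-joined strings.
parse_lick_column <- function(col) {
  if (is.list(col)) return(lapply(col, function(v) as.numeric(v %||% numeric())))
  lapply(as.character(col), function(s) {
    if (is.na(s) || !nzchar(s)) numeric() else as.numeric(strsplit(s, ";")[[1]])
  })
}

#' Apply session-level exclusions (satiation, truncated windows)
#'
#' Two rules. (1) Satiation: within the latter half of the session, if the
#' response probability on the easiest trial type (largest target-zone
#' count) falls below `sated_threshold` in a 10-trial sliding window of
#' easiest-type trials centred on each such trial, the animal is deemed
#' sated at the first offending trial and all later trials are excluded.
#' (2) Edge truncation: trials whose pre-onset baseline or post-onset
#' response window extends beyond the recorded span are excluded with
#' reason `"window_truncated"`.
#'
#' @param trials scored trials (see [score_trials()]).
#' @param sated_threshold response-rate floor for the easiest type.
#' @param window_trials width of the sliding window (easiest-type trials).
#' @param recording_span_s optional numeric length-2 `c(start, end)` of the
#'   usable recording; `NULL` skips the truncation rule.
#' @param pre_s,post_s margins required around each onset when
#'   `recording_span_s` is given.
#' @return trials with satiated/truncated trials re-marked `excluded`.
#' @export
apply_session_exclusions <- function(trials, sated_threshold = 0.7,
                                     window_trials = 10L,
                                     recording_span_s = NULL,
                                     pre_s = 1, post_s = 1.15) {
  stopifnot(is.data.frame(trials), "outcome" %in% names(trials))
  n <- nrow(trials)

  if (!is.null(recording_span_s)) {
    bad <- trials$onset_s - pre_s < recording_span_s[1] |
      trials$onset_s + post_s > recording_span_s[2]
    trials$outcome[bad] <- "excluded"
    trials$exclusion_reason[bad] <- "window_truncated"
  }

  go_types <- trials$trial_type[trials$trial_type > 0]
  if (length(go_types) == 0L) return(trials)
  easiest <- max(go_types)
  idx_easy <- which(trials$trial_type == easiest & trials$outcome != "excluded")
  if (length(idx_easy) < window_trials) {
    warning("apply_session_exclusions(): fewer than ", window_trials,
            " easiest-type trials; satiation rule skipped", call. = FALSE)
    return(trials)
  }
  resp <- as.numeric(trials$outcome[idx_easy] == "hit")
  half <- floor(window_trials / 2)
  sated_at <- NA_integer_
  for (k in seq_along(idx_easy)) {
    if (idx_easy[k] <= n / 2) next  # rule applies to the latter session half
    lo <- k - (half - 1L); hi <- k + half  # centred: 4 before, self, 5 after
    if (lo < 1L || hi > length(idx_easy)) next
    if (mean(resp[lo:hi]) < sated_threshold) { sated_at <- idx_easy[k]; break }
  }
  if (!is.na(sated_at)) {
    late <- which(seq_len(n) > sated_at)
    trials$outcome[late] <- "excluded"
    trials$exclusion_reason[late] <- "sated"
    attr(trials, "sated_at_trial") <- sated_at
  }
  trials
}

#' Response probability for a trial type
#'
#' `P(response) = n_lick / (n_lick + n_nolick)` over non-excluded trials of
#' the type. With `catch_subtract = TRUE` the catch-trial response rate is
#' subtracted from the go-trial rate.
#'
#' @param trials scored trials.
#' @param trial_type the type to summarise (0 = catch).
#' @param catch_subtract subtract the catch response rate?
#' @return a probability (possibly negative if catch-subtracted).
#' @export
response_rate <- function(trials, trial_type, catch_subtract = FALSE) {
  p <- raw_rate(trials, trial_type)
  if (!catch_subtract) return(p)
  p - raw_rate(trials, 0)
}

raw_rate <- function(trials, type) {
  sel <- trials$trial_type == type & trials$outcome != "excluded"
  abort_if(sum(sel) == 0L,
           sprintf("response_rate(): no eligible trials of type %s", type))
  mean(trials$outcome[sel] %in% c("hit", "false_alarm"))
}

#' Signal-detection sensitivity (d-prime)
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`, with the standard
#' boundary correction replacing rates of 0 with `1/(2N)` and rates of 1
#' with `1 - 1/(2N)` (N = number of trials behind the rate).
#'
#' @param hit_rate,fa_rate rates in \[0, 1\].
#' @param n_go,n_catch trial counts behind each rate.
#' @return d-prime (unitless).
#' @export
d_prime <- function(hit_rate, fa_rate, n_go, n_catch) {
  abort_if(n_go <= 0 || n_catch <= 0, "d_prime(): trial counts must be > 0")
  abort_if(hit_rate < 0 || hit_rate > 1 || fa_rate < 0 || fa_rate > 1,
           "d_prime(): rates must be in [0, 1]")
  h <- correct_rate(hit_rate, n_go)
  f <- correct_rate(fa_rate, n_catch)
  stats::qnorm(h) - stats::qnorm(f)
}

correct_rate <- function(r, n) {
  if (r <= 0) 1 / (2 * n) else if (r >= 1) 1 - 1 / (2 * n) else r
}

#' Reaction-time statistics for a trial type
#'
#' Mean and sample SD of reaction times over response trials of the type.
#' Undefined (all-NA with `defined = FALSE`) when there are two or fewer
#' responses, matching the session-inclusion rule that all trial types must
#' have responses on more than two trials.
#'
#' @param trials scored trials.
#' @param trial_type the type to summarise.
#' @return list with `mean_s`, `sd_s`, `n_responses`, `defined`.
#' @export
reaction_time_stats <- function(trials, trial_type) {
  sel <- trials$trial_type == trial_type & trials$outcome %in% c("hit", "false_alarm")
  rts <- trials$reaction_time_s[sel]
  rts <- rts[!is.na(rts)]
  if (length(rts) <= 2L) {
    return(list(mean_s = NA_real_, sd_s = NA_real_,
                n_responses = length(rts), defined = FALSE))
  }
  list(mean_s = mean(rts), sd_s = stats::sd(rts),
       n_responses = length(rts), defined = TRUE)
}

#' Per-type behavioural summary
#'
#' Convenience wrapper: P(response), catch-subtracted P(response), trial
#' counts, reaction-time statistics and d-prime (vs catch) for every go
#' type present, plus the catch row.
#'
#' @param trials scored trials.
#' @return data.frame, one row per trial type.
#' @export
behavior_summary <- function(trials) {
  types <- sort(unique(trials$trial_type))
  has_catch <- 0 %in% types
  p_catch <- if (has_catch) raw_rate(trials, 0) else NA_real_
  n_catch <- sum(trials$trial_type == 0 & trials$outcome != "excluded")
  rows <- lapply(types, function(tt) {
    sel <- trials$trial_type == tt & trials$outcome != "excluded"
    p <- raw_rate(trials, tt)
    rt <- reaction_time_stats(trials, tt)
    dp <- if (tt > 0 && has_catch && n_catch > 0)
      d_prime(p, p_catch, sum(sel), n_catch) else NA_real_
    data.frame(trial_type = tt, n_trials = sum(sel), p_response = p,
               p_response_catch_subtracted = if (tt > 0 && has_catch) p - p_catch else NA_real_,
               rt_mean_s = rt$mean_s, rt_sd_s = rt$sd_s, d_prime = dp)
  })
  do.call(rbind, rows)
}
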