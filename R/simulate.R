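#' Configuration for a synthetic all-optical session
#'
#' Collects every generative parameter of the simulator with defaults that
#' mirror the experimental design: trial types are catch (0 zones) plus go
#' stimuli of 5--200 target zones in the ratios 15\% catch, 15\% easy
#' 200-zone trials and ~11.7\% for each of the six smaller types; imaging
#' is a 4-plane volume at 6.69 Hz (26.8 Hz plane rate); behaviour follows a
#' log-normal psychometric curve whose ground truth defaults to a 50\%
#' point near 21 activated neurons. Neuron count is desk-scaled (hundreds,
#' not thousands) so that a full session simulates in seconds.
#'
#' Transient amplitudes are expressed in trial-wise dF/sigmaF response
#' units: the exponential calcium kernel is normalised so that its mean
#' over the response window (0.7--1.0 s post event) is 1, hence an
#' amplitude of `a` plants an expected windowed response of `a` baseline
#' SDs.
#'
#' @param n_neurons number of ROIs.
#' @param fov_size_um lateral field-of-view size (square).
#' @param n_planes,plane_spacing_um axial sampling.
#' @param volume_rate_hz volumetric imaging rate.
#' @param trial_type_set integer target-zone counts; 0 denotes catch.
#' @param trial_ratios per-type proportions (same order; sums to 1).
#' @param n_trials number of main (post warm-up) trials.
#' @param n_warmup leading block of easy trials prepended to the sequence.
#' @param iti_mean_s,iti_jitter_s inter-trial onset spacing: uniform in
#'   `mean +/- jitter`.
#' @param psych_truth list `(m, w, lambda, gamma)`: ground-truth
#'   psychometric parameters generating lick behaviour.
#' @param rt_median_s,rt_sigma log-normal reaction-time parameters.
#' @param p_target_activation per-target per-trial activation probability.
#' @param suppression_base,suppression_slope background per-neuron
#'   suppression probability: `base + slope * n_activated_targets`.
#' @param frac_lick_modulated fraction of neurons with lick-coupled
#'   transients.
#' @param transient_amplitude_sd_units planted target-activation response
#'   amplitude (dF/sigmaF units).
#' @param suppression_amplitude_sd_units planted suppression dip amplitude
#'   (negative).
#' @param lick_amplitude_sd_units lick-coupled transient amplitude.
#' @param transient_tau_s calcium-kernel decay constant.
#' @param spont_event_rate_hz spontaneous transient rate per neuron (free
#'   parameter; not asserted by any experimental value).
#' @param spont_bout_rate_hz rate of spontaneous inter-trial lick bouts.
#' @param neuropil_coeff_true generative neuropil contamination
#'   coefficient in \[0.5, 1\].
#' @param noise_sd,baseline_offset,drift_amplitude,drift_period_s baseline
#'   fluorescence model: Gaussian noise on a positive offset plus a slow
#'   sinusoidal drift.
#' @param seed master seed; all sub-generators derive independent streams
#'   from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_neurons = 400,
                       fov_size_um = 500,
                       n_planes = 4,
                       plane_spacing_um = 33,
                       volume_rate_hz = 6.69,
                       trial_type_set = c(0, 5, 10, 25, 50, 75, 100, 200),
                       trial_ratios = c(0.15, rep(0.7 / 6, 6), 0.15),
                       n_trials = 100,
                       n_warmup = 10,
                       iti_mean_s = 10,
                       iti_jitter_s = 3,
                       psych_truth = list(m = log(21), w = 1.25,
                                          lambda = 0.05, gamma = 0.05),
                       rt_median_s = 0.56,
                       rt_sigma = 0.25,
                       p_target_activation = 0.5,
                       suppression_base = 0.02,
                       suppression_slope = 3e-3,
                       frac_lick_modulated = 0.1,
                       transient_amplitude_sd_units = 5,
                       suppression_amplitude_sd_units = -1.5,
                       lick_amplitude_sd_units = 2,
                       transient_tau_s = 1,
                       spont_event_rate_hz = 0.01,
                       spont_bout_rate_hz = 0.03,
                       neuropil_coeff_true = 0.7,
                       noise_sd = 1,
                       baseline_offset = 100,
                       drift_amplitude = 2,
                       drift_period_s = 120,
                       seed = 1L) {
  cfg <- as.list(environment())
  abort_if(abs(sum(trial_ratios) - 1) > 1e-9,
           "sim_config(): trial_ratios must sum to 1")
  abort_if(length(trial_ratios) != length(trial_type_set),
           "sim_config(): one ratio per trial type required")
  abort_if(n_planes < 1 || volume_rate_hz <= 0,
           "sim_config(): need n_planes >= 1 and volume_rate_hz > 0")
  probs <- c(p_target_activation, suppression_base, frac_lick_modulated,
             psych_truth$lambda, psych_truth$gamma)
  abort_if(any(probs < 0 | probs > 1), "sim_config(): probabilities must be in [0, 1]")
  abort_if(psych_truth$w <= 0, "sim_config(): psych_truth$w must be > 0")
  abort_if(neuropil_coeff_true < 0.5 || neuropil_coeff_true > 1,
           "sim_config(): neuropil_coeff_true must be in [0.5, 1]")
  abort_if(max(trial_type_set) >= n_neurons,
           "sim_config(): need more neurons than the largest target count")
  structure(cfg, class = "sim_config")
}

#' Generate a pseudorandom trial sequence
#'
#' Exact per-type trial counts (largest-remainder rounding of the ratios)
#' are interleaved pseudorandomly under a three-trial upper limit on
#' consecutive trials of the same type, after an initial warm-up buffer of
#' easy (largest-zone-count) trials. Trial onsets are spaced uniformly in
#' `iti_mean_s +/- iti_jitter_s`, starting 10 s into the recording.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed (defaults to the sequence stream of the config
#'   master seed).
#' @param max_run maximum consecutive same-type trials (warm-up excluded).
#' @return data.frame with `trial_index`, `trial_type`, `onset_s`,
#'   `warmup`.
#' @export
generate_trial_sequence <- function(config, seed = NULL, max_run = 3L) {
  seed <- seed %||% derive_seed(config$seed, "sequence")
  types <- config$trial_type_set
  counts <- largest_remainder(config$trial_ratios, config$n_trials)
  # an arrangement with run length <= max_run exists iff the most frequent
  # type can be separated by the others
  cmax <- max(counts)
  abort_if(cmax > max_run * (config$n_trials - cmax + 1),
           sprintf(paste0("generate_trial_sequence(): infeasible: %d trials of one ",
                          "type cannot be arranged in %d trials with run length <= %d"),
                   cmax, config$n_trials, max_run))
  local_seed(seed, {
    seq_types <- place_with_run_limit(rep(types, counts), max_run)
    easy <- max(types[types > 0])
    all_types <- c(rep(easy, config$n_warmup), seq_types)
    n <- length(all_types)
    iti <- stats::runif(n - 1, config$iti_mean_s - config$iti_jitter_s,
                        config$iti_mean_s + config$iti_jitter_s)
    data.frame(trial_index = seq_len(n),
               trial_type = all_types,
               onset_s = 10 + c(0, cumsum(iti)),
               warmup = rep(c(TRUE, FALSE), c(config$n_warmup, length(seq_types))))
  })
}

# first lick of each run of licks separated by > 1 s
bout_starts <- function(licks) {
  if (length(licks) == 0L) return(numeric())
  licks[c(TRUE, diff(licks) > 1)]
}

largest_remainder <- function(ratios, n) {
  exact <- ratios * n
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    add <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1L
  }
  as.integer(counts)
}

# Random shuffle under a run-length cap by sequential sampling with
# rejection restarts (restarts are rare for balanced compositions).
place_with_run_limit <- function(pool, max_run, max_restarts = 1000L) {
  for (r in seq_len(max_restarts)) {
    remaining <- table(pool)
    out <- numeric(length(pool))
    run_type <- NA; run_len <- 0L; ok <- TRUE
    for (i in seq_along(pool)) {
      cand <- names(remaining)[remaining > 0]
      if (run_len >= max_run) cand <- setdiff(cand, as.character(run_type))
      if (length(cand) == 0L) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else
        sample(cand, 1, prob = remaining[cand])
      out[i] <- as.numeric(pick)
      remaining[pick] <- remaining[pick] - 1L
      if (identical(as.numeric(pick), as.numeric(run_type))) {
        run_len <- run_len + 1L
      } else {
        run_type <- as.numeric(pick); run_len <- 1L
      }
    }
    if (ok) return(out)
  }
  stop("place_with_run_limit(): could not satisfy the run-length constraint",
       call. = FALSE)
}

#' Plant per-trial target activation
#'
#' Designates the (nested) target-neuron sets and draws, for every go
#' trial, which targets actually activate (independent Bernoulli draws
#' with probability `p_target_activation` per target). The zone sets nest:
#' the k-zone stimulus targets the first k neurons of the easy-type
#' ordering, as in experiments where smaller stimuli are subsets of the
#' 200-neuron group.
#'
#' @param sequence trial sequence from [generate_trial_sequence()].
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return list with `target_ids` (neuron indices, easy-type ordering),
#'   `activated` (list, per trial, of activated neuron indices) and
#'   `n_activated` (per-trial counts; 0 on catch).
#' @export
plan_target_activation <- function(sequence, config, seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, "activation")
  n_max <- max(config$trial_type_set)
  local_seed(seed, {
    target_ids <- sample.int(config$n_neurons, n_max)
    activated <- vector("list", nrow(sequence))
    for (i in seq_len(nrow(sequence))) {
      k <- sequence$trial_type[i]
      if (k == 0) { activated[[i]] <- integer(); next }
      zone_neurons <- target_ids[seq_len(k)]
      hit <- stats::runif(k) < config$p_target_activation
      activated[[i]] <- zone_neurons[hit]
    }
    list(target_ids = target_ids, activated = activated,
         n_activated = vapply(activated, length, integer(1)))
  })
}

#' Plant per-trial background suppression events
#'
#' Draws, for every trial, which background (non-target for that trial's
#' type) neurons receive a suppression dip: independent Bernoulli draws
#' with probability `suppression_base + suppression_slope * n_activated`.
#' Drawn on its own RNG stream so recovery tests can access the planted
#' events without synthesising traces.
#'
#' @param sequence trial sequence.
#' @param plan activation plan from [plan_target_activation()].
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return neurons x trials logical matrix of planted dips.
#' @export
plan_suppression_events <- function(sequence, plan, config, seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, "suppression")
  nn <- config$n_neurons
  n_trials <- nrow(sequence)
  local_seed(seed, {
    events <- matrix(FALSE, nrow = nn, ncol = n_trials)
    for (i in seq_len(n_trials)) {
      k <- sequence$trial_type[i]
      is_target <- rep(FALSE, nn)
      if (k > 0) is_target[plan$target_ids[seq_len(k)]] <- TRUE
      p_sup <- min(1, config$suppression_base +
                     config$suppression_slope * plan$n_activated[i])
      bg <- which(!is_target)
      events[bg[stats::runif(length(bg)) < p_sup], i] <- TRUE
    }
    events
  })
}

#' Generate lick behaviour from the ground-truth psychometric curve
#'
#' Each go trial elicits a lick with probability `psi(x_true)` where
#' `x_true` is the planted number of activated targets (the lower-asymptote
#' limit `gamma` when none activated); catch trials lick with probability
#' `gamma`. Reaction times are log-normal (median `rt_median_s`, log-SD
#' `rt_sigma`) clipped to the response window, and a short lick bout at
#' ~7 Hz follows the first lick. Spontaneous inter-trial lick bouts are
#' drawn at a low Poisson rate (`spont_bout_rate_hz`) and attached as the
#' `"spont_licks_s"` attribute, one vector of bout lick times -- lick
#' modulation analyses need licking outside trial periods.
#'
#' @param sequence trial sequence.
#' @param psych_truth list `(m, w, lambda, gamma)`.
#' @param x_true per-trial activated-target counts (0 for catch).
#' @param seed RNG seed.
#' @param config a `sim_config` (reaction-time parameters).
#' @param response_window scoring window (s post onset).
#' @return the sequence data.frame with `lick_times_s` (list-column),
#'   `licked`, `x_true` and an all-`NA` `autoreward_s` column.
#' @export
generate_behavior <- function(sequence, psych_truth, x_true, seed = NULL,
                              config = sim_config(),
                              response_window = c(0.15, 1.15)) {
  check_psych_params(psych_truth$m, psych_truth$w, psych_truth$lambda,
                     psych_truth$gamma)
  seed <- seed %||% derive_seed(config$seed, "behavior")
  n <- nrow(sequence)
  abort_if(length(x_true) != n, "generate_behavior(): x_true length mismatch")
  local_seed(seed, {
    p_lick <- psychometric(x_true, psych_truth$m, psych_truth$w,
                           psych_truth$lambda, psych_truth$gamma)
    p_lick[sequence$trial_type == 0] <- psych_truth$gamma
    licked <- stats::runif(n) < p_lick
    licks <- vector("list", n)
    for (i in seq_len(n)) {
      if (!licked[i]) { licks[[i]] <- numeric(); next }
      rt <- stats::rlnorm(1, meanlog = log(config$rt_median_s),
                          sdlog = config$rt_sigma)
      rt <- min(max(rt, response_window[1] + 0.01), response_window[2] - 0.01)
      bout <- rt + cumsum(c(0, stats::rexp(4, rate = 7)))
      licks[[i]] <- sequence$onset_s[i] + bout
    }
    sequence$lick_times_s <- licks
    sequence$licked <- licked
    sequence$x_true <- x_true
    sequence$autoreward_s <- NA_real_
    # spontaneous lick bouts in the inter-trial background
    t_end <- max(sequence$onset_s) + 5
    n_bouts <- stats::rpois(1, config$spont_bout_rate_hz * t_end)
    spont <- sort(stats::runif(n_bouts, 5, t_end))
    spont_licks <- unlist(lapply(spont, function(t0) {
      t0 + cumsum(c(0, stats::rexp(sample(2:4, 1), rate = 7)))
    }))
    attr(sequence, "spont_licks_s") <- sort(spont_licks %||% numeric())
    sequence
  })
}

#' Generate ROI and neuropil fluorescence traces
#'
#' Builds a volumetric timebase covering all trials with at least 1 s
#' before the first and 8 s after the last onset, then synthesises, per
#' neuron: a neuropil trace (shared slow sinusoidal drift plus noise), and
#' a raw ROI trace `c_true * neuropil + offset + noise + transients`.
#' Planted transients are: positive target-activation responses on the
#' activated targets of each trial, negative-going suppression dips on
#' background neurons (per-trial Bernoulli with probability
#' `base + slope * n_activated`), lick-coupled transients at lick bouts
#' for a signed subset of neurons, and spontaneous events at a low Poisson
#' rate. All transients share an exponential decay kernel (tau
#' `transient_tau_s`) normalised to unit mean over the response window.
#'
#' @param sequence behaviour-annotated trial table.
#' @param plan activation plan from [plan_target_activation()].
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @param suppression_events planted dips from [plan_suppression_events()]
#'   (drawn with the default stream when omitted).
#' @return list with `f_roi`, `f_neuropil` (neurons x volumes),
#'   `volume_times_s`, `centroids_um`, `plane_index`, `lick_coupling`
#'   (signed per-neuron amplitude, 0 = uncoupled) and `suppression_events`
#'   (neurons x trials logical matrix of planted dips).
#' @export
generate_traces <- function(sequence, plan, config, seed = NULL,
                            suppression_events = NULL) {
  seed <- seed %||% derive_seed(config$seed, "traces")
  dt <- 1 / config$volume_rate_hz
  t_end <- max(sequence$onset_s) + 8
  volume_times <- seq(0, t_end, by = dt)
  abort_if(min(sequence$onset_s) < volume_times[1] + 1,
           "generate_traces(): need >= 1 s of recording before the first onset")
  nv <- length(volume_times)
  nn <- config$n_neurons
  n_trials <- nrow(sequence)

  # kernel: unit mean over the response window used downstream
  decay <- exp(-dt / config$transient_tau_s)
  k_window <- config$transient_tau_s *
    (exp(-0.7 / config$transient_tau_s) - exp(-1.0 / config$transient_tau_s)) / 0.3
  amp_scale <- 1 / k_window

  suppression_events <- suppression_events %||%
    plan_suppression_events(sequence, plan, config)
  spont_licks <- attr(sequence, "spont_licks_s") %||% numeric()

  local_seed(seed, {
    centroids <- cbind(x = stats::runif(nn, 0, config$fov_size_um),
                       y = stats::runif(nn, 0, config$fov_size_um),
                       z = (sample.int(config$n_planes, nn, replace = TRUE) - 1) *
                         config$plane_spacing_um)
    plane_index <- centroids[, "z"] / config$plane_spacing_um + 1

    shared_np <- config$baseline_offset / 2 +
      config$drift_amplitude * sin(2 * pi * volume_times / config$drift_period_s) +
      stats::rnorm(nv, sd = config$noise_sd / 2)
    f_neuropil <- matrix(rep(shared_np, each = nn), nrow = nn)

    # signed lick coupling for a random subset of neurons
    coupled <- stats::runif(nn) < config$frac_lick_modulated
    coupling <- numeric(nn)
    coupling[coupled] <- config$lick_amplitude_sd_units *
      ifelse(stats::runif(sum(coupled)) < 0.8, 1, -1)

    # per-neuron impulse trains on the volume grid
    impulses <- matrix(0, nrow = nn, ncol = nv)
    add_event <- function(neuron, time_s, amp) {
      v <- findInterval(time_s, volume_times) + 1L
      if (v >= 1L && v <= nv) impulses[neuron, v] <<- impulses[neuron, v] + amp
    }

    for (i in seq_len(n_trials)) {
      for (nrn in plan$activated[[i]]) {
        add_event(nrn, sequence$onset_s[i], config$transient_amplitude_sd_units)
      }
      for (nrn in which(suppression_events[, i])) {
        add_event(nrn, sequence$onset_s[i], config$suppression_amplitude_sd_units)
      }
    }

    # lick-coupled transients at lick bouts: first lick of each trial bout
    # and every spontaneous bout onset
    coupled_ids <- which(coupling != 0)
    bout_onsets <- c(
      unlist(lapply(sequence$lick_times_s, function(lt) if (length(lt)) lt[1])),
      bout_starts(spont_licks))
    for (b in bout_onsets) {
      for (nrn in coupled_ids) add_event(nrn, b, coupling[nrn])
    }

    # spontaneous events
    n_spont <- stats::rpois(nn, config$spont_event_rate_hz * t_end)
    for (nrn in which(n_spont > 0)) {
      for (ts in stats::runif(n_spont[nrn], 0, t_end)) {
        add_event(nrn, ts, config$transient_amplitude_sd_units / 2)
      }
    }

    transients <- t(apply(impulses, 1L, function(x) {
      as.numeric(stats::filter(x, decay, method = "recursive"))
    })) * amp_scale * config$noise_sd

    f_roi <- config$neuropil_coeff_true * f_neuropil +
      config$baseline_offset / 2 +
      matrix(stats::rnorm(nn * nv, sd = config$noise_sd), nrow = nn) +
      transients

    list(f_roi = f_roi, f_neuropil = f_neuropil,
         volume_times_s = volume_times, centroids_um = centroids,
         plane_index = plane_index, lick_coupling = coupling,
         suppression_events = suppression_events)
  })
}

#' Simulate a complete synthetic session
#'
#' Runs the generative stages in order -- trial sequence, target-activation
#' plan, lick behaviour, fluorescence traces -- each on its own RNG stream
#' derived from the master seed, and assembles the session bundle together
#' with the ground truth needed for parameter-recovery tests.
#'
#' @param config a `sim_config`.
#' @param traces generate fluorescence traces (set `FALSE` for
#'   behaviour-only sessions, which is much faster).
#' @return object of class `sim_session`: list with `config`, `trials`,
#'   `targets` (per-type zone coordinates), `traces` (or `NULL`) and
#'   `ground_truth`.
#' @export
simulate_session <- function(config = sim_config(), traces = TRUE) {
  sequence <- generate_trial_sequence(config)
  plan <- plan_target_activation(sequence, config)
  trials <- generate_behavior(sequence, config$psych_truth, plan$n_activated,
                              config = config)
  sup_events <- plan_suppression_events(trials, plan, config)
  tr <- if (traces) generate_traces(trials, plan, config,
                                    suppression_events = sup_events) else NULL

  zone_tab <- NULL
  if (traces) {
    go_types <- sort(setdiff(config$trial_type_set, 0))
    zone_tab <- do.call(rbind, lapply(go_types, function(k) {
      ids <- plan$target_ids[seq_len(k)]
      data.frame(trial_type = k,
                 x_um = tr$centroids_um[ids, "x"],
                 y_um = tr$centroids_um[ids, "y"],
                 z_um = tr$centroids_um[ids, "z"])
    }))
  }

  structure(list(
    config = config, trials = trials, targets = zone_tab, traces = tr,
    spont_licks_s = attr(trials, "spont_licks_s"),
    ground_truth = list(
      psych_truth = config$psych_truth,
      target_ids = plan$target_ids,
      activated = plan$activated,
      per_trial_activated_targets = plan$n_activated,
      suppression_base = config$suppression_base,
      suppression_slope = config$suppression_slope,
      suppression_events = sup_events,
      frac_lick_modulated = config$frac_lick_modulated,
      per_neuron_lick_coupling = if (traces) tr$lick_coupling else NULL,
      neuropil_coeff_true = config$neuropil_coeff_true
    )
  ), class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("Synthetic all-optical session: %d trials (%d warm-up), %d neurons\n",
              nrow(x$trials), sum(x$trials$warmup), x$config$n_neurons))
  cat(sprintf("  trial types: %s\n",
              paste(x$config$trial_type_set, collapse = ", ")))
  if (!is.null(x$traces)) {
    cat(sprintf("  traces: %d volumes at %.2f Hz\n",
                length(x$traces$volume_times_s), x$config$volume_rate_hz))
  }
  invisible(x)
}
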