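# Synthetic-session generator: trial sequences, behaviour, traces.

test_that("trial sequence honours exact ratios, warm-up block and run-length cap", {
  cfg <- sim_config(n_trials = 200, seed = 41)
  seq1 <- generate_trial_sequence(cfg)

  # warm-up: leading block of easy (largest) trials, flagged
  expect_equal(sum(seq1$warmup), cfg$n_warmup)
  expect_true(all(seq1$trial_type[seq1$warmup] == 200))
  expect_true(all(which(seq1$warmup) == seq_len(cfg$n_warmup)))

  # exact largest-remainder composition of the main block
  main <- seq1$trial_type[!seq1$warmup]
  counts <- table(factor(main, levels = cfg$trial_type_set))
  exact <- cfg$trial_ratios * cfg$n_trials
  expect_true(all(abs(as.numeric(counts) - exact) < 1))
  expect_equal(sum(counts), cfg$n_trials)

  # run-length cap on the main block
  runs <- rle(main)
  expect_lte(max(runs$lengths), 3L)

  # onset spacing uniform in mean +/- jitter
  iti <- diff(seq1$onset_s)
  expect_true(all(iti >= cfg$iti_mean_s - cfg$iti_jitter_s - 1e-9))
  expect_true(all(iti <= cfg$iti_mean_s + cfg$iti_jitter_s + 1e-9))
})

test_that("trial sequence generation is deterministic and errors on infeasible input", {
  cfg <- sim_config(n_trials = 100, seed = 7)
  expect_identical(generate_trial_sequence(cfg), generate_trial_sequence(cfg))

  cfg_bad <- sim_config(trial_type_set = c(0, 10), trial_ratios = c(0, 1),
                        n_trials = 4, seed = 1)
  expect_error(generate_trial_sequence(cfg_bad), "infeasible")
})

test_that("planted activation counts match n_zones * p per type (3 binomial SEs)", {
  cfg <- fast_config(seed = 13, n_trials = 300, p_target_activation = 0.5)
  seqs <- generate_trial_sequence(cfg)
  plan <- plan_target_activation(seqs, cfg)
  for (tt in c(10, 50, 100)) {
    idx <- which(seqs$trial_type == tt)
    m <- mean(plan$n_activated[idx])
    se <- sqrt(tt * 0.5 * 0.5) / sqrt(length(idx))
    expect_lt(abs(m - tt * 0.5), 3 * se)
  }
  # never more activated targets than zones
  expect_true(all(plan$n_activated <= seqs$trial_type))
})

test_that("lick behaviour follows the ground-truth psychometric curve", {
  truth <- list(m = log(21), w = 1.25, lambda = 0.05, gamma = 0.05)
  levels <- c(5, 10, 25, 50, 75, 100)
  n_per <- 2000
  seqs <- data.frame(trial_index = seq_len(n_per * length(levels) + n_per),
                     trial_type = c(rep(levels, each = n_per), rep(0, n_per)),
                     onset_s = seq_len(n_per * length(levels) + n_per) * 10,
                     warmup = FALSE)
  x_true <- ifelse(seqs$trial_type > 0, seqs$trial_type, 0)
  beh <- generate_behavior(seqs, truth, x_true, seed = 99, config = sim_config())

  # Monte-Carlo agreement with the psi evaluator at each level
  for (lv in levels) {
    p_hat <- mean(beh$licked[beh$trial_type == lv])
    p_true <- psychometric(lv, truth$m, truth$w, truth$lambda, truth$gamma)
    expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / n_per))
  }
  # catch trials lick at the guess rate
  p_catch <- mean(beh$licked[beh$trial_type == 0])
  expect_lt(abs(p_catch - truth$gamma),
            4 * sqrt(truth$gamma * (1 - truth$gamma) / n_per))
})

test_that("behaviour hits asymptotes in the degenerate limits", {
  truth0 <- list(m = log(21), w = 1.25, lambda = 0, gamma = 0)
  seqs <- data.frame(trial_index = 1:500, trial_type = rep(10, 500),
                     onset_s = (1:500) * 10, warmup = FALSE)
  beh_hi <- generate_behavior(seqs, truth0, rep(1e6, 500), seed = 1,
                              config = sim_config())
  expect_equal(mean(beh_hi$licked), 1)  # psi -> 1 as x -> Inf with lambda = 0
  beh_lo <- generate_behavior(seqs, truth0, rep(0, 500), seed = 1,
                              config = sim_config())
  expect_equal(mean(beh_lo$licked), 0)  # gamma = 0 floor
  # reaction times live inside the response window
  rts <- unlist(lapply(beh_hi$lick_times_s, function(l) l[1])) - beh_hi$onset_s
  expect_true(all(rts > 0.15 & rts < 1.15))
})

test_that("full session generation is byte-identical under one seed", {
  cfg <- fast_config(seed = 5, n_trials = 40)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$traces$f_roi, s2$traces$f_roi)
  expect_identical(s1$trials$lick_times_s, s2$trials$lick_times_s)
  expect_identical(s1$ground_truth$suppression_events,
                   s2$ground_truth$suppression_events)
})

test_that("planted neuropil coefficient is recovered from generated traces", {
  cfg <- fast_config(seed = 21, n_trials = 40, neuropil_coeff_true = 0.7,
                     n_neurons = 40, trial_type_set = c(0, 5, 10, 25),
                     trial_ratios = c(0.15, 0.35, 0.35, 0.15))
  s <- simulate_session(cfg)
  excl <- artefact_exclusion_mask(s$trials$onset_s, s$traces$volume_times_s)
  mask <- rep(FALSE, length(s$traces$volume_times_s))
  mask[excl[excl >= 1 & excl <= length(mask)]] <- TRUE
  coefs <- vapply(1:40, function(i) {
    estimate_neuropil_coefficient(s$traces$f_roi[i, ], s$traces$f_neuropil[i, ],
                                  exclude_mask = mask)
  }, numeric(1))
  expect_lt(abs(median(coefs, na.rm = TRUE) - 0.7), 0.05)
})

test_that("p_target_activation = 1 with large amplitude activates every target", {
  cfg <- fast_config(seed = 3, n_trials = 60, p_target_activation = 1,
                     transient_amplitude_sd_units = 50,
                     spont_event_rate_hz = 0, frac_lick_modulated = 0)
  s <- simulate_session(cfg)
  res <- analyze_session(s, n_perm_calib = 100, seed = 2,
                         estimate_neuropil = FALSE)
  go <- which(res$trials$trial_type > 0 & res$trials$outcome != "excluded")
  for (i in go) {
    k <- res$trials$trial_type[i]
    planted <- s$ground_truth$target_ids[seq_len(k)]
    expect_true(all(res$classification[planted, i] == "activated"))
  }
})

test_that("zero suppression slope yields a flat background suppression trend", {
  cfg <- fast_config(seed = 17, n_trials = 100, suppression_slope = 0)
  seqs <- generate_trial_sequence(cfg)
  plan <- plan_target_activation(seqs, cfg)
  ev <- plan_suppression_events(seqs, plan, cfg)
  types <- setdiff(cfg$trial_type_set, 0)
  pts <- t(vapply(types, function(tt) {
    idx <- which(seqs$trial_type == tt & !seqs$warmup)
    n_bg <- cfg$n_neurons - tt
    c(x = mean(plan$n_activated[idx]),
      y = mean(colSums(ev[, idx, drop = FALSE])) / n_bg)
  }, numeric(2)))
  fit <- linear_trend(pts[, "x"], pts[, "y"])
  expect_true(fit$ci[1] <= 0 && fit$ci[2] >= 0)
})
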