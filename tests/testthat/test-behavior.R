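# Trial scoring, exclusions, response rates, d-prime, reaction times.

test_that("score_trials assigns outcomes, reaction times and fast-lick exclusions", {
  tr <- make_raw_trials(
    trial_type = c(10, 10, 10, 0, 0, 10),
    onset_s = c(10, 20, 30, 40, 50, 60),
    licks = list(10.5,        # hit at RT 0.50
                 20.10,       # first lick at 0.10 -> excluded
                 numeric(),   # miss
                 40.4,        # false alarm
                 numeric(),   # correct reject
                 31 + 31))    # lick far outside window -> miss
  sc <- score_trials(tr)
  expect_equal(as.character(sc$outcome),
               c("hit", "excluded", "miss", "false_alarm", "correct_reject", "miss"))
  expect_equal(sc$reaction_time_s[1], 0.5)
  expect_equal(sc$reaction_time_s[4], 0.4)
  expect_equal(sc$exclusion_reason[2], "rt_too_fast")
  # scored reaction times always exceed the 0.15 s floor
  expect_true(all(sc$reaction_time_s > 0.15, na.rm = TRUE))
})

test_that("auto-rewarded trials are scored conservatively", {
  tr <- make_raw_trials(rep(10, 3), c(10, 20, 30),
                        list(10.55, 20.70, numeric()))
  tr$autoreward_s <- 0.5
  sc <- score_trials(tr)
  # lick before autoreward + 0.15 -> hit; later lick in window -> still miss
  expect_equal(as.character(sc$outcome), c("hit", "miss", "miss"))
})

test_that("score_trials validates lick times", {
  expect_error(score_trials(make_raw_trials(10, 10, list(c(12, 11)))), "sorted")
  expect_error(score_trials(make_raw_trials(10, 10, list(-1))), "negative")
})

test_that("outcome partition always covers the session", {
  for (seed in 1:5) {
    cfg <- fast_config(seed = seed, n_trials = 60)
    s <- simulate_session(cfg, traces = FALSE)
    sc <- score_trials(s$trials)
    counts <- table(sc$outcome)
    expect_equal(sum(counts), nrow(sc))
    # go trials are hit/miss, catch trials FA/CR (when not excluded)
    go <- sc$trial_type > 0 & sc$outcome != "excluded"
    expect_true(all(sc$outcome[go] %in% c("hit", "miss")))
    catch <- sc$trial_type == 0 & sc$outcome != "excluded"
    expect_true(all(sc$outcome[catch] %in% c("false_alarm", "correct_reject")))
  }
})

test_that("satiation rule truncates at the brute-force oracle's trial", {
  # 40 trials, easiest type 100 interleaved with type 10; craft easiest-type
  # responses to collapse in the second half
  n <- 40
  type <- rep(c(100, 10), n / 2)
  easy_resp <- c(rep(1, 10), 1, 1, 0, 0, 0, 0, 0, 0, 1, 0)  # 20 easiest trials
  licks <- vector("list", n)
  ei <- 0
  for (i in seq_len(n)) {
    if (type[i] == 100) {
      ei <- ei + 1
      licks[[i]] <- if (easy_resp[ei] == 1) i * 10 + 0.5 else numeric()
    } else licks[[i]] <- numeric()
  }
  sc <- score_trials(make_raw_trials(type, (1:n) * 10, licks))
  ex <- apply_session_exclusions(sc)

  # independent oracle: centred 10-trial windows (4 before, self, 5 after)
  # over easiest-type trials, first trial in the latter half with mean < 0.7
  easy_idx <- which(type == 100)
  oracle <- NA
  for (k in seq_along(easy_idx)) {
    if (easy_idx[k] <= n / 2) next
    if (k - 4 < 1 || k + 5 > length(easy_idx)) next
    if (mean(easy_resp[(k - 4):(k + 5)]) < 0.7) { oracle <- easy_idx[k]; break }
  }
  expect_false(is.na(oracle))
  expect_equal(attr(ex, "sated_at_trial"), oracle)
  expect_true(all(ex$outcome[seq_len(n) > oracle] == "excluded"))
  expect_true(all(ex$exclusion_reason[seq_len(n) > oracle] == "sated"))
  expect_true(all(ex$outcome[seq_len(oracle)] != "excluded" |
                    sc$outcome[seq_len(oracle)] == "excluded"))
})

test_that("no truncation at ceiling performance; too-few-easy warns", {
  type <- rep(c(100, 10), 20)
  licks <- lapply(seq_along(type), function(i)
    if (type[i] == 100) i * 10 + 0.5 else numeric())
  sc <- score_trials(make_raw_trials(type, seq_along(type) * 10, licks))
  ex <- apply_session_exclusions(sc)
  expect_null(attr(ex, "sated_at_trial"))
  expect_true(all(ex$outcome != "excluded"))

  few <- score_trials(make_raw_trials(c(100, 10, 10), c(10, 20, 30),
                                      list(10.5, numeric(), numeric())))
  expect_warning(apply_session_exclusions(few), "satiation")
})

test_that("edge-truncated trials are excluded with reason", {
  sc <- score_trials(make_raw_trials(c(10, 10), c(5, 99.6), list(5.5, numeric())))
  ex <- suppressWarnings(apply_session_exclusions(sc, recording_span_s = c(0, 100)))
  expect_equal(as.character(ex$outcome[2]), "excluded")
  expect_equal(ex$exclusion_reason[2], "window_truncated")
  expect_equal(as.character(ex$outcome[1]), "hit")
})

test_that("response_rate computes the licked fraction and catch subtraction", {
  tr <- make_trials(c(rep(10, 10), rep(0, 8)),
                    c(rep("hit", 6), rep("miss", 4),
                      "false_alarm", rep("correct_reject", 7)))
  expect_equal(response_rate(tr, 10), 0.6)
  expect_equal(response_rate(tr, 0), 0.125)
  expect_equal(response_rate(tr, 10, catch_subtract = TRUE), 0.6 - 0.125)
  # floor case and the zero-eligible error are distinct
  tr0 <- make_trials(rep(10, 8), rep("miss", 8))
  expect_equal(response_rate(tr0, 10), 0)
  expect_error(response_rate(tr0, 25), "no eligible")
  # excluded trials never contribute
  tr$outcome[1] <- "excluded"
  expect_equal(response_rate(tr, 10), 5 / 9)
})

test_that("response rate is invariant to trial order", {
  tr <- make_trials(rep(10, 9), c(rep("hit", 4), rep("miss", 5)))
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(response_rate(perm, 10), response_rate(tr, 10))
})

test_that("d-prime matches analytic quantiles and the boundary correction", {
  # hit = Phi(1), fa = Phi(-1) -> d' = 2 exactly
  expect_equal(d_prime(pnorm(1), pnorm(-1), 100, 100), 2, tolerance = 1e-10)
  expect_equal(d_prime(0.5, 0.5, 10, 10), 0)
  # 1-1/(2N) correction, frozen from a hand computation:
  # qnorm(1 - 1/40) - qnorm(0.1) = 1.959964 + 1.281552 = 3.241516
  expect_equal(d_prime(1, 0.1, 20, 20), qnorm(0.975) - qnorm(0.1),
               tolerance = 1e-12)
  expect_equal(d_prime(1, 0.1, 20, 20), 3.241516, tolerance = 1e-6)
  # rate-0 correction on the false-alarm side
  expect_equal(d_prime(0.8, 0, 20, 25), qnorm(0.8) - qnorm(1 / 50),
               tolerance = 1e-12)
  expect_error(d_prime(0.5, 0.5, 0, 10), "> 0")
})

test_that("d-prime is antisymmetric and monotone in hit rate", {
  expect_equal(d_prime(0.9, 0.2, 50, 50), -d_prime(0.2, 0.9, 50, 50))
  hs <- seq(0.05, 0.95, by = 0.05)
  ds <- vapply(hs, d_prime, numeric(1), fa_rate = 0.2, n_go = 50, n_catch = 50)
  expect_true(all(diff(ds) > 0))
})

test_that("reaction-time statistics require more than two responses", {
  tr <- make_trials(rep(10, 3), rep("hit", 3), reaction_time_s = c(0.4, 0.5, 0.6))
  st <- reaction_time_stats(tr, 10)
  expect_true(st$defined)
  expect_equal(st$mean_s, 0.5)
  expect_equal(st$sd_s, 0.1)

  tr2 <- make_trials(c(10, 10, 10), c("hit", "hit", "miss"),
                     reaction_time_s = c(0.4, 0.5, NA))
  expect_false(reaction_time_stats(tr2, 10)$defined)
  expect_false(reaction_time_stats(make_trials(10, "miss"), 10)$defined)
})

test_that("behavior_summary aggregates rates, RT stats and d-prime per type", {
  cfg <- fast_config(seed = 11, n_trials = 120)
  s <- simulate_session(cfg, traces = FALSE)
  sc <- score_trials(s$trials)
  bs <- behavior_summary(sc)
  expect_setequal(bs$trial_type, cfg$trial_type_set)
  expect_true(all(bs$p_response >= 0 & bs$p_response <= 1))
  # catch-subtracted equals the go rate minus the catch rate
  p_catch <- bs$p_response[bs$trial_type == 0]
  expect_equal(bs$p_response_catch_subtracted[bs$trial_type > 0],
               bs$p_response[bs$trial_type > 0] - p_catch)
  # easy trials should outperform the hardest in this stated world
  expect_gt(bs$p_response[bs$trial_type == 100],
            bs$p_response[bs$trial_type == 5])
})
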