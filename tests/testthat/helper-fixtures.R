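# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so failures reproduce.

# neurons x trials matrix of null responses with heterogeneous per-neuron
# Gaussian distributions (no signal).
gaussian_null_responses <- function(n_neurons, n_trials, seed,
                                    mu_sd = 0.3, log_sigma_sd = 0.3) {
  withr_seed(seed, {
    mu <- rnorm(n_neurons, 0, mu_sd)
    sig <- exp(rnorm(n_neurons, 0, log_sigma_sd))
    mu + sig * matrix(rnorm(n_neurons * n_trials), nrow = n_neurons)
  })
}

# minimal local stand-in for withr::with_seed
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# a scored-trials data.frame built directly (bypasses score_trials)
make_trials <- function(trial_type, outcome, reaction_time_s = NA_real_) {
  n <- length(trial_type)
  data.frame(trial_index = seq_len(n), trial_type = trial_type,
             onset_s = seq_len(n) * 10,
             outcome = factor(outcome, levels = c("hit", "miss", "false_alarm",
                                                  "correct_reject", "excluded")),
             reaction_time_s = rep_len(reaction_time_s, n),
             exclusion_reason = NA_character_)
}

# raw (unscored) trial table from onset + per-trial lick vectors
make_raw_trials <- function(trial_type, onset_s, licks) {
  df <- data.frame(trial_index = seq_along(trial_type),
                   trial_type = trial_type, onset_s = onset_s)
  df$lick_times_s <- licks
  df
}

# small config for fast full-pipeline sessions
fast_config <- function(seed, ...) {
  defaults <- list(n_neurons = 250, n_trials = 80,
                   trial_type_set = c(0, 5, 10, 25, 50, 75, 100),
                   trial_ratios = c(0.15, rep(0.7 / 5, 5), 0.15),
                   seed = seed)
  extra <- list(...)
  do.call(sim_config, utils::modifyList(defaults, extra))
}
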