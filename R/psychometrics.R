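#' Log-normal psychometric function
#'
#' Probability of a behavioural response (lick) as a function of stimulus
#' strength `x` (number of activated target neurons), modelled as a
#' cumulative Gaussian in log stimulus space with fixed guess and lapse
#' asymptotes:
#' \deqn{\psi(x; m, w, \lambda, \gamma) = \gamma + (1-\lambda-\gamma)\,
#'   S(x; m, w), \quad S(x; m, w) = \Phi\!\left(C\,\frac{\log x - m}{w}\right)}
#' where \eqn{C = \Phi^{-1}(0.95) - \Phi^{-1}(0.05)} so that `w` is the
#' width of the sigmoid between its 5\% and 95\% points in natural-log
#' stimulus units, and `m` is the log stimulus at the 50\% point of `S`.
#'
#' `x = 0` is accepted and returns the lower asymptote `gamma` (the
#' \eqn{x \to 0^+} limit), so catch trials can be evaluated on the same
#' curve; negative `x` is an error.
#'
#' @param x stimulus magnitude(s), `>= 0` (e.g. number of activated targets).
#' @param m threshold parameter: natural-log stimulus at the midpoint of `S`.
#' @param w width parameter (5--95\% width in log units), `> 0`.
#' @param lambda lapse rate: upper asymptote is `1 - lambda`.
#' @param gamma guess rate: lower asymptote.
#' @return numeric vector of response probabilities.
#' @examples
#' psychometric(exp(1.5), m = 1.5, w = 1, lambda = 0, gamma = 0)  # 0.5
#' @export
psychometric <- function(x, m, w, lambda = 0, gamma = 0) {
  check_psych_params(m, w, lambda, gamma)
  abort_if(any(x < 0), "psychometric(): x must be >= 0")
  C <- psych_C()
  s <- ifelse(x == 0, 0, stats::pnorm(C * (log(pmax(x, .Machine$double.xmin)) - m) / w))
  gamma + (1 - lambda - gamma) * s
}

# The 5-95% probit span used to parameterise the width.
psych_C <- function() stats::qnorm(0.95) - stats::qnorm(0.05)

check_psych_params <- function(m, w, lambda, gamma) {
  abort_if(!is_scalar_num(m), "psychometric parameters: m must be a finite scalar")
  abort_if(!is_scalar_num(w) || w <= 0, "psychometric parameters: w must be > 0")
  abort_if(lambda < 0 || gamma < 0 || lambda + gamma >= 1,
           "psychometric parameters: need lambda >= 0, gamma >= 0, lambda + gamma < 1")
  invisible(TRUE)
}

#' Scaled (asymptote-free) sigmoid S(x; m, w)
#'
#' The guess/lapse-free component of [psychometric()]. Curve landmarks
#' (10/50/90\% points) are defined on `S`, not on `psi`.
#'
#' @inheritParams psychometric
#' @export
psychometric_S <- function(x, m, w) {
  abort_if(any(x <= 0), "psychometric_S(): x must be > 0")
  stats::pnorm(psych_C() * (log(x) - m) / w)
}

#' Fit the psychometric function by weighted binomial maximum likelihood
#'
#' Fits threshold `m` and width `w` while the lapse rate `lambda` and guess
#' rate `gamma` are held fixed (in the experiments these are fixed at
#' `1 - max P(lick)` over stimulus types and at the catch-trial response
#' rate, respectively; see [fix_asymptotes()]). Only go (stimulus) trials
#' enter the fit. The objective is the weighted binomial log-likelihood of
#' `n_lick` responses out of `n_trials` at probability `psi(x)`; weights
#' default to 1 (trial counts already weight each point) and can carry
#' per-session trial totals for aggregate fits.
#'
#' Optimisation is bounded quasi-Newton (`L-BFGS-B`) from multiple starts on
#' a coarse (m, w) grid. 95\% confidence intervals for `m` and `w` are by
#' nonparametric bootstrap over datapoints. A fit whose width lands on the
#' upper bound is flagged (`w_at_bound`), never silently returned as good.
#'
#' @param x stimulus levels (positive; one per datapoint).
#' @param n_lick number of response (lick) trials per datapoint.
#' @param n_trials total trials per datapoint.
#' @param lambda,gamma fixed asymptote parameters.
#' @param weights optional positive per-datapoint weights.
#' @param n_boot bootstrap resamples for the CIs (0 to skip).
#' @param w_max upper bound for the width parameter.
#' @param n_starts grid starts per parameter (total starts = n_starts^2).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `psychometric_fit`: list with `m`, `w`,
#'   `lambda`, `gamma`, `C`, `ci_m`, `ci_w`, `r2`, `loglik`, `w_at_bound`,
#'   and the datapoints used.
#' @export
fit_psychometric <- function(x, n_lick, n_trials, lambda = 0, gamma = 0,
                             weights = NULL, n_boot = 1000, w_max = 50,
                             n_starts = 5, seed = NULL) {
  abort_if(length(x) < 2L || length(unique(x)) < 2L,
           "fit_psychometric(): need >= 2 distinct stimulus levels")
  abort_if(any(x <= 0), "fit_psychometric(): stimulus levels must be > 0")
  abort_if(length(n_lick) != length(x) || length(n_trials) != length(x),
           "fit_psychometric(): x, n_lick, n_trials must have equal length")
  abort_if(any(n_trials <= 0) || any(n_lick < 0) || any(n_lick > n_trials),
           "fit_psychometric(): need 0 <= n_lick <= n_trials, n_trials > 0")
  check_psych_params(0, 1, lambda, gamma)
  weights <- weights %||% rep(1, length(x))
  abort_if(any(weights <= 0), "fit_psychometric(): weights must be positive")

  opt <- optimize_psych(x, n_lick, n_trials, lambda, gamma, weights,
                        w_max = w_max, n_starts = n_starts)

  p_obs <- n_lick / n_trials
  p_hat <- psychometric(x, opt$m, opt$w, lambda, gamma)
  ss_tot <- sum((p_obs - stats::weighted.mean(p_obs, weights))^2 * weights)
  r2 <- if (ss_tot > 0) 1 - sum((p_obs - p_hat)^2 * weights) / ss_tot else NA_real_

  ci_m <- ci_w <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(x), replace = TRUE)
        if (length(unique(x[idx])) < 2L) return(c(NA_real_, NA_real_))
        ob <- optimize_psych(x[idx], n_lick[idx], n_trials[idx], lambda, gamma,
                             weights[idx], w_max = w_max, n_starts = 3)
        c(ob$m, ob$w)
      }, numeric(2))
    })
    ci_m <- unname(stats::quantile(boots[1, ], c(0.025, 0.975), na.rm = TRUE))
    ci_w <- unname(stats::quantile(boots[2, ], c(0.025, 0.975), na.rm = TRUE))
  }

  structure(list(
    m = opt$m, w = opt$w, lambda = lambda, gamma = gamma, C = psych_C(),
    ci_m = ci_m, ci_w = ci_w, r2 = r2, loglik = opt$loglik,
    w_at_bound = opt$w >= w_max * (1 - 1e-6),
    data = data.frame(x = x, n_lick = n_lick, n_trials = n_trials,
                      weight = weights)
  ), class = "psychometric_fit")
}

# Weighted binomial negative log-likelihood of (m, w); used by the fitter
# and by the grid-search oracle in the tests.
psych_negll <- function(par, x, n_lick, n_trials, lambda, gamma, weights) {
  p <- gamma + (1 - lambda - gamma) *
    stats::pnorm(psych_C() * (log(x) - par[1]) / par[2])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(weights * (n_lick * log(p) + (n_trials - n_lick) * log(1 - p)))
}

optimize_psych <- function(x, n_lick, n_trials, lambda, gamma, weights,
                           w_max = 50, n_starts = 5) {
  lx <- log(x)
  lower <- c(min(lx) - 3, 1e-2)
  upper <- c(max(lx) + 3, w_max)
  m_grid <- seq(min(lx), max(lx), length.out = n_starts)
  w_grid <- exp(seq(log(0.2), log(min(w_max, 10)), length.out = n_starts))
  best <- NULL
  for (m0 in m_grid) for (w0 in w_grid) {
    fit <- tryCatch(
      stats::optim(c(m0, w0), psych_negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 10),  # ~1e-8 relative ll tolerance
                   x = x, n_lick = n_lick, n_trials = n_trials,
                   lambda = lambda, gamma = gamma, weights = weights),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  abort_if(is.null(best), "fit_psychometric(): optimisation failed at every start")
  list(m = best$par[1], w = best$par[2], loglik = -best$value)
}

#' Fix lapse and guess rates from observed response rates
#'
#' The lapse rate is fixed as `1 - max(P(lick))` over go stimulus types and
#' the guess rate as the catch-trial response rate.
#'
#' @param p_go named/ordered vector of go-trial response rates by type.
#' @param p_catch catch-trial response rate.
#' @return list with `lambda` and `gamma`.
#' @export
fix_asymptotes <- function(p_go, p_catch) {
  abort_if(length(p_go) < 1L || any(p_go < 0 | p_go > 1),
           "fix_asymptotes(): p_go must be rates in [0, 1]")
  abort_if(p_catch < 0 || p_catch > 1, "fix_asymptotes(): p_catch in [0, 1]")
  lambda <- 1 - max(p_go)
  gamma <- p_catch
  if (lambda + gamma >= 1) {
    stop("fix_asymptotes(): lambda + gamma >= 1; data cannot constrain a curve",
         call. = FALSE)
  }
  list(lambda = lambda, gamma = gamma)
}

#' Stimulus levels at given points of the scaled curve
#'
#' Returns the stimulus values at which the scaled sigmoid `S` (not `psi`)
#' reaches the requested probabilities: `x_p = exp(m + (w/C) * qnorm(p))`.
#' The default levels give the detection threshold (10\%), midpoint (50\%)
#' and saturation (90\%) in units of activated neurons.
#'
#' @param fit a `psychometric_fit` (or any list with `m`, `w`).
#' @param levels probabilities in (0, 1).
#' @return named numeric vector of stimulus values.
#' @export
curve_points <- function(fit, levels = c(0.1, 0.5, 0.9)) {
  abort_if(any(levels <= 0 | levels >= 1), "curve_points(): levels must be in (0, 1)")
  out <- exp(fit$m + (fit$w / psych_C()) * stats::qnorm(levels))
  names(out) <- paste0("x", round(levels * 100))
  out
}

#' Slope of the psychometric function at its midpoint
#'
#' The derivative of `psi` with respect to `x`, evaluated at the 50\% point
#' of the scaled curve (`x50 = exp(m)`): the additional probability of
#' detection added per extra activated target neuron at the steepest part of
#' the curve. Closed form:
#' \deqn{\frac{d\psi}{dx}\Big|_{x_{50}} = (1-\lambda-\gamma)\,
#'   \frac{C}{w\, x_{50}\sqrt{2\pi}}.}
#' The slope of the scaled curve `S` (ignoring asymptotes) is available via
#' `scaled = TRUE`.
#'
#' @param fit a `psychometric_fit`.
#' @param scaled if `TRUE`, slope of `S` rather than of `psi`.
#' @return slope in probability per unit stimulus.
#' @export
slope_at_midpoint <- function(fit, scaled = FALSE) {
  C <- psych_C()
  x50 <- exp(fit$m)
  s <- C / (fit$w * x50 * sqrt(2 * pi))
  if (scaled) s else (1 - fit$lambda - fit$gamma) * s
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Log-normal psychometric fit\n")
  cat(sprintf("  m = %.4f (x50 = %.2f), w = %.4f\n", x$m, exp(x$m), x$w))
  cat(sprintf("  lambda = %.3f (fixed), gamma = %.3f (fixed)\n", x$lambda, x$gamma))
  if (!all(is.na(x$ci_m))) {
    cat(sprintf("  95%% CI m: [%.4f, %.4f], w: [%.4f, %.4f]\n",
                x$ci_m[1], x$ci_m[2], x$ci_w[1], x$ci_w[2]))
  }
  cat(sprintf("  r2 = %.3f on %d datapoints%s\n", x$r2, nrow(x$data),
              if (isTRUE(x$w_at_bound)) "  [width at bound]" else ""))
  invisible(x)
}

#' Cross-validated prediction of behaviour from a neural predictor
#'
#' Tests how well a neural variable (e.g. hit:miss-matched mean number of
#' activated targets per session and trial type) predicts the recorded
#' P(lick), by repeatedly refitting the psychometric threshold and width on
#' random 80:20 train:test splits of the datapoints while `lambda` and
#' `gamma` stay fixed at values computed from all data. Reports train and
#' test R-squared distributions and permutation p-values against zero
#' (fraction of splits with R-squared <= 0).
#'
#' Proportion-valued predictors can be zero; a small positivity floor
#' `eps` is added before the log-domain fit.
#'
#' @param predictor positive predictor value per datapoint.
#' @param n_lick,n_trials observed response counts per datapoint.
#' @param lambda,gamma fixed asymptotes (from all data).
#' @param n_perm number of random splits.
#' @param train_frac fraction of datapoints in the training set.
#' @param eps positivity floor added to the predictor.
#' @param seed RNG seed.
#' @return object of class `crossval_result` with `r2_train`, `r2_test`
#'   vectors, medians, and `p_train`, `p_test`.
#' @export
crossval_predict <- function(predictor, n_lick, n_trials, lambda = 0, gamma = 0,
                             n_perm = 10000, train_frac = 0.8, eps = 1e-4,
                             seed = NULL) {
  n <- length(predictor)
  abort_if(n < 5L, "crossval_predict(): need >= 5 datapoints")
  abort_if(any(predictor < 0), "crossval_predict(): predictor must be >= 0")
  x <- predictor + eps
  p_obs <- n_lick / n_trials
  n_train <- max(2L, round(train_frac * n))
  n_train <- min(n_train, n - 1L)

  res <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      repeat {
        tr <- sample.int(n, n_train)
        if (length(unique(x[tr])) >= 2L) break
      }
      te <- setdiff(seq_len(n), tr)
      fit <- optimize_psych(x[tr], n_lick[tr], n_trials[tr], lambda, gamma,
                            rep(1, n_train), n_starts = 3)
      r2_of <- function(idx) {
        p_hat <- psychometric(x[idx], fit$m, fit$w, lambda, gamma)
        ss_tot <- sum((p_obs[idx] - mean(p_obs[idx]))^2)
        if (ss_tot == 0) return(NA_real_)
        1 - sum((p_obs[idx] - p_hat)^2) / ss_tot
      }
      c(r2_of(tr), r2_of(te))
    }, numeric(2))
  })
  r2_train <- res[1, ]
  r2_test <- res[2, ]
  structure(list(
    r2_train = r2_train, r2_test = r2_test,
    median_r2_train = stats::median(r2_train, na.rm = TRUE),
    median_r2_test = stats::median(r2_test, na.rm = TRUE),
    p_train = mean(r2_train <= 0, na.rm = TRUE),
    p_test = mean(r2_test <= 0, na.rm = TRUE),
    n_perm = n_perm, train_frac = train_frac
  ), class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf(
    "Cross-validated psychometric prediction (%d permutations, %.0f:%.0f split)\n",
    x$n_perm, 100 * x$train_frac, 100 * (1 - x$train_frac)))
  cat(sprintf("  median train R2 = %.3f (p = %.4g)\n", x$median_r2_train, x$p_train))
  cat(sprintf("  median test  R2 = %.3f (p = %.4g)\n", x$median_r2_test, x$p_test))
  invisible(x)
}
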