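# Psychometric evaluation, fitting, curve landmarks, cross-validation.

test_that("psi respects its closed-form identities and limits", {
  m <- log(21); w <- 1.25
  # midpoint and width definition
  expect_equal(psychometric(exp(m), m, w), 0.5, tolerance = 1e-12)
  expect_equal(psychometric_S(exp(m + w / 2), m, w), 0.95, tolerance = 1e-12)
  expect_equal(psychometric_S(exp(m - w / 2), m, w), 0.05, tolerance = 1e-12)
  # limits: gamma at 0, 1 - lambda at infinity
  expect_equal(psychometric(0, m, w, lambda = 0.1, gamma = 0.07), 0.07)
  expect_equal(psychometric(1e12, m, w, lambda = 0.1, gamma = 0.07), 0.9,
               tolerance = 1e-9)
  # asymptote mixing
  expect_equal(psychometric(exp(m), m, w, lambda = 0.1, gamma = 0.06),
               0.06 + (1 - 0.1 - 0.06) / 2, tolerance = 1e-12)
  # monotone in x
  xs <- exp(seq(1.2, 4.4, length.out = 100))  # away from numerical saturation
  expect_true(all(diff(psychometric(xs, m, w, 0.05, 0.05)) > 0))
  expect_error(psychometric(-1, m, w), ">= 0")
  expect_error(psychometric(10, m, -1), "w must be")
  expect_error(psychometric(10, m, w, lambda = 0.6, gamma = 0.5), "lambda")
})

test_that("curve points invert S and are log-symmetric", {
  fit <- list(m = log(21), w = 1.4)
  cp <- curve_points(fit)
  expect_equal(unname(cp["x50"]), 21, tolerance = 1e-12)
  # log symmetry: x90/x50 = x50/x10
  expect_equal(cp[["x90"]] / cp[["x50"]], cp[["x50"]] / cp[["x10"]],
               tolerance = 1e-10)
  # bisection oracle: S(x_p) = p
  for (p in c(0.1, 0.5, 0.9)) {
    root <- uniroot(function(x) psychometric_S(x, fit$m, fit$w) - p,
                    c(1e-3, 1e5), tol = 1e-12)$root
    expect_equal(unname(cp[paste0("x", p * 100)]), root, tolerance = 1e-6)
  }
  expect_error(curve_points(fit, levels = 1.2), "levels")
})

test_that("midpoint slope matches a central finite difference to 1e-6 relative", {
  fit <- list(m = log(15), w = 1.1, lambda = 0.08, gamma = 0.04)
  x50 <- exp(fit$m)
  h <- x50 * 1e-6
  fd <- (psychometric(x50 + h, fit$m, fit$w, fit$lambda, fit$gamma) -
           psychometric(x50 - h, fit$m, fit$w, fit$lambda, fit$gamma)) / (2 * h)
  expect_equal(slope_at_midpoint(fit), fd, tolerance = 1e-6)
  # unit reduction: lambda = gamma = 0, m = 0, w = C -> slope 1/sqrt(2*pi) at x = 1
  C <- qnorm(0.95) - qnorm(0.05)
  expect_equal(slope_at_midpoint(list(m = 0, w = C, lambda = 0, gamma = 0)),
               1 / sqrt(2 * pi), tolerance = 1e-12)
  # slope strictly decreasing in w
  slopes <- vapply(c(0.5, 1, 2, 4), function(w)
    slope_at_midpoint(list(m = 2, w = w, lambda = 0, gamma = 0)), numeric(1))
  expect_true(all(diff(slopes) < 0))
  # scaled-curve slope ignores the asymptotes
  expect_equal(slope_at_midpoint(fit, scaled = TRUE),
               slope_at_midpoint(fit) / (1 - fit$lambda - fit$gamma))
})

test_that("noiseless data on a psi curve are fit exactly", {
  m <- log(18); w <- 1.3; lambda <- 0.06; gamma <- 0.08
  x <- c(5, 10, 25, 50, 75, 100)
  n <- rep(1000, 6)
  k <- round(n * psychometric(x, m, w, lambda, gamma))
  fit <- fit_psychometric(x, k, n, lambda, gamma, n_boot = 0)
  expect_lt(abs(fit$m - m), 0.02)
  expect_lt(abs(fit$w - w), 0.06)
  expect_gt(fit$r2, 0.999)
  expect_false(fit$w_at_bound)
})

test_that("the optimiser beats a dense grid search", {
  withr_seed(61, {
    x <- c(5, 10, 25, 50, 75, 100)
    p <- psychometric(x, log(21), 1.25, 0.05, 0.05)
    k <- rbinom(6, 30, p)
  })
  fit <- fit_psychometric(x, k, rep(30, 6), 0.05, 0.05, n_boot = 0)
  grid <- expand.grid(m = seq(log(2), log(200), length.out = 60),
                      w = seq(0.05, 6, length.out = 60))
  grid_best <- min(apply(grid, 1, function(g)
    optodetect:::psych_negll(c(g[1], g[2]), x, k, rep(30, 6), 0.05, 0.05,
                             rep(1, 6))))
  expect_lte(-fit$loglik, grid_best + 1e-6)
})

test_that("equal weights reproduce the unweighted fit; CIs cover the truth", {
  withr_seed(62, {
    x <- c(5, 10, 25, 50, 75, 100)
    k <- rbinom(6, 200, psychometric(x, log(21), 1.25, 0, 0))
  })
  f1 <- fit_psychometric(x, k, rep(200, 6), n_boot = 0)
  f2 <- fit_psychometric(x, k, rep(200, 6), weights = rep(3.7, 6), n_boot = 0)
  expect_equal(f1$m, f2$m, tolerance = 1e-6)
  expect_equal(f1$w, f2$w, tolerance = 1e-6)
  f3 <- fit_psychometric(x, k, rep(200, 6), n_boot = 200, seed = 9)
  expect_true(f3$ci_m[1] <= log(21) && log(21) <= f3$ci_m[2])
})

test_that("fit input validation catches bad data", {
  expect_error(fit_psychometric(c(5, 5), c(1, 2), c(10, 10)), "distinct")
  expect_error(fit_psychometric(c(-5, 10), c(1, 2), c(10, 10)), "> 0")
  expect_error(fit_psychometric(c(5, 10), c(11, 2), c(10, 10)), "n_lick")
})

test_that("asymptote fixing follows the max-stimulus and catch rates", {
  fx <- fix_asymptotes(p_go = c(0.2, 0.6, 0.92), p_catch = 0.11)
  expect_equal(fx$lambda, 1 - 0.92)
  expect_equal(fx$gamma, 0.11)
  expect_error(fix_asymptotes(c(0.05), 0.96), "cannot constrain")
})

test_that("aggregate fits are no steeper than the mean individual fit", {
  # two heterogeneous sessions generated exactly on psi curves
  x <- c(5, 10, 25, 50, 75, 100)
  sess <- list(list(m = log(10), w = 1.0), list(m = log(45), w = 1.0))
  slopes <- numeric(2)
  pooled_x <- c(); pooled_k <- c(); pooled_n <- c()
  for (i in 1:2) {
    p <- psychometric(x, sess[[i]]$m, sess[[i]]$w)
    k <- round(500 * p)
    slopes[i] <- slope_at_midpoint(fit_psychometric(x, k, rep(500, 6), n_boot = 0))
    pooled_x <- c(pooled_x, x); pooled_k <- c(pooled_k, k)
    pooled_n <- c(pooled_n, rep(500, 6))
  }
  agg <- fit_psychometric(pooled_x, pooled_k, pooled_n, n_boot = 0)
  expect_lte(slope_at_midpoint(agg), mean(slopes) + 1e-9)
})

test_that("cross-validation separates a perfect predictor from noise", {
  withr_seed(71, {
    x <- rep(c(2, 5, 10, 20, 40, 80), 3) * exp(rnorm(18, 0, 0.1))
    p <- psychometric(x, log(21), 1.25, 0.05, 0.05)
    k <- rbinom(18, 40, p)
    noise <- runif(18, 1, 100)
  })
  cv_good <- crossval_predict(x, k, rep(40, 18), 0.05, 0.05,
                              n_perm = 300, seed = 5)
  expect_gt(cv_good$median_r2_test, 0)
  expect_lt(cv_good$p_test, 0.05)
  cv_noise <- crossval_predict(noise, k, rep(40, 18), 0.05, 0.05,
                               n_perm = 300, seed = 5)
  expect_lte(cv_noise$median_r2_test, 0)
  expect_gt(cv_noise$p_test, 0.05)
  expect_error(crossval_predict(1:4, 1:4, rep(10, 4)), ">= 5")
})
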