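test_that("exactly collinear trials give a perfect, zero-residual fit", {
  x <- c(-0.8, -0.5, -0.2, 0.1, 0.3)
  eff <- toy_effects(x, 0.8 * x + 0.1)
  fit <- fit_trial_regression(eff$dfs, eff$os, weights_scheme = "equal")
  expect_equal(fit$slope, 0.8, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$resid_scale, 0, tolerance = 1e-7)
})

test_that("weighting is invariant to a common scale and matches lm()", {
  x <- c(-0.9, -0.4, -0.1, 0.2, 0.5, -0.6)
  y <- c(-0.7, -0.5, 0.1, 0.1, 0.4, -0.3)
  # equal n per trial: n_total weights collapse to equal weights
  eff_eq <- toy_effects(x, y, n = rep(80L, 6))
  f1 <- fit_trial_regression(eff_eq$dfs, eff_eq$os, "n_total")
  f2 <- fit_trial_regression(eff_eq$dfs, eff_eq$os, "equal")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$r, f2$r, tolerance = 1e-12)

  # independent oracle: weighted lm on the same data
  n <- c(40L, 200L, 90L, 150L, 60L, 120L)
  eff <- toy_effects(x, y, n = n)
  fit <- fit_trial_regression(eff$dfs, eff$os, "n_total")
  lmfit <- lm(y ~ x, weights = n / mean(n))
  expect_equal(fit$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_equal(unname(fit$cov), unname(vcov(lmfit)), tolerance = 1e-10)
  expect_equal(fit$resid_scale, summary(lmfit)$sigma, tolerance = 1e-10)
})

test_that("trial-level regression rejects degenerate inputs", {
  eff <- toy_effects(c(-0.5, -0.2), c(-0.4, -0.1))
  expect_error(fit_trial_regression(eff$dfs, eff$os), ">= 3")
  flat <- toy_effects(rep(-0.5, 4), c(-0.4, -0.3, -0.2, -0.1))
  expect_error(fit_trial_regression(flat$dfs, flat$os), "zero variance")
})

test_that("fitted r is calibrated against the generator's trial correlation", {
  rs <- vapply(1:500, function(s) {
    truth <- meta_truth(n_trials = 7, trial_corr = 0.85, seed = 3000 + s)
    ros <- draw_trial_effects(truth)
    eff <- toy_effects(ros$true_loghr_dfs, ros$true_loghr_os,
                       n = ros$n_control + ros$n_experimental)
    fit_trial_regression(eff$dfs, eff$os, "n_total")$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.85), 0.1)
})

test_that("prediction intervals match the weighted least-squares oracle", {
  x <- c(-0.9, -0.5, -0.2, 0.1, 0.4)
  y <- c(-0.8, -0.3, -0.3, 0.2, 0.3)
  n <- c(100L, 150L, 80L, 120L, 90L)
  eff <- toy_effects(x, y, n = n)
  fit <- fit_trial_regression(eff$dfs, eff$os, "n_total")
  # brute-force WLS covariance algebra
  w <- n / mean(n)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% diag(w) %*% X) %*% t(X) %*% diag(w) %*% y
  s2 <- sum(w * (y - X %*% beta)^2) / 3
  covb <- s2 * solve(t(X) %*% diag(w) %*% X)
  for (x0 in c(-1, -0.3, 0.5)) {
    pr <- predict_os_effect(fit, x0, n_new = 110)
    v <- s2 / (110 / mean(n)) + c(1, x0) %*% covb %*% c(1, x0)
    lo <- beta[1] + beta[2] * x0 - qt(0.975, 3) * sqrt(v)
    hi <- beta[1] + beta[2] * x0 + qt(0.975, 3) * sqrt(v)
    expect_equal(pr$lo, as.numeric(lo), tolerance = 1e-6)
    expect_equal(pr$hi, as.numeric(hi), tolerance = 1e-6)
  }

  # width is minimized near the weighted predictor mean and grows outward
  xbar <- sum(w * x) / sum(w)
  width <- function(x0) { p <- predict_os_effect(fit, x0); p$hi - p$lo }
  xs <- xbar + seq(0, 2, by = 0.25)
  expect_true(all(diff(vapply(xs, width, numeric(1))) > 0))
  xs_l <- xbar - seq(0, 2, by = 0.25)
  expect_true(all(diff(vapply(xs_l, width, numeric(1))) > 0))
})

test_that("surrogate threshold effect brackets 1 and matches a grid search", {
  x <- c(-0.9, -0.6, -0.3, 0.0, 0.3)
  y <- c(-0.75, -0.55, -0.2, 0.05, 0.25)
  eff <- toy_effects(x, y)
  fit <- fit_trial_regression(eff$dfs, eff$os, "equal")
  ste <- compute_ste(fit)
  expect_lte(ste$ste_beneficial, 1)
  expect_gte(ste$ste_harmful, 1)

  # brute-force oracle: scan the upper prediction limit on a fine grid
  tq <- qt(0.975, fit$df)
  upper <- function(z) fit$intercept + fit$slope * z +
    tq * sqrt(fit$sigma2 + rowSums((cbind(1, z) %*% fit$cov) * cbind(1, z)))
  z <- seq(ste$x_beneficial - 1e-3, ste$x_beneficial + 1e-3, by = 1e-7)
  sign_flip <- z[which(diff(sign(upper(z))) != 0)[1]]
  expect_lt(abs(exp(sign_flip) - ste$ste_beneficial), 1e-3)

  lower <- function(z) fit$intercept + fit$slope * z -
    tq * sqrt(fit$sigma2 + rowSums((cbind(1, z) %*% fit$cov) * cbind(1, z)))
  z <- seq(ste$x_harmful - 1e-3, ste$x_harmful + 1e-3, by = 1e-7)
  sign_flip <- z[which(diff(sign(lower(z))) != 0)[1]]
  expect_lt(abs(exp(sign_flip) - ste$ste_harmful), 1e-3)
})

test_that("STE degenerates to 1 for a perfect surrogate and shrinks with noise", {
  # exact line y = x with no residual: prediction limits collapse onto it
  x <- c(-0.6, -0.3, 0.0, 0.2, 0.5)
  eff <- toy_effects(x, x)
  fit <- fit_trial_regression(eff$dfs, eff$os, "equal")
  ste <- compute_ste(fit)
  expect_equal(ste$ste_beneficial, 1, tolerance = 1e-6)
  expect_equal(ste$ste_harmful, 1, tolerance = 1e-6)

  # shrinking the residual scale moves the beneficial STE toward 1
  y <- x + c(0.05, -0.04, 0.03, -0.05, 0.02)
  eff2 <- toy_effects(x, y)
  fit2 <- fit_trial_regression(eff2$dfs, eff2$os, "equal")
  stes <- vapply(c(1, 0.5, 0.2, 0.05), function(f) {
    shrunk <- fit2
    shrunk$sigma2 <- fit2$sigma2 * f^2
    shrunk$resid_scale <- fit2$resid_scale * f
    shrunk$cov <- fit2$cov * f^2
    compute_ste(shrunk)$ste_beneficial
  }, numeric(1))
  expect_true(all(diff(stes) > 0))

  # non-concordant slope: undefined with a warning
  effn <- toy_effects(x, -x + c(0.02, -0.01, 0.03, 0, -0.02))
  fitn <- fit_trial_regression(effn$dfs, effn$os, "equal")
  expect_warning(sten <- compute_ste(fitn), "not positive")
  expect_true(is.na(sten$ste_beneficial) && is.na(sten$ste_harmful))
})

test_that("r is invariant under a common rescaling of all effects", {
  x <- c(-0.9, -0.4, -0.1, 0.2, 0.5)
  y <- c(-0.7, -0.5, 0.1, 0.1, 0.4)
  eff <- toy_effects(x, y)
  f1 <- fit_trial_regression(eff$dfs, eff$os, "equal")
  effc <- toy_effects(2.5 * x, 2.5 * y)
  f2 <- fit_trial_regression(effc$dfs, effc$os, "equal")
  expect_equal(f2$r, f1$r, tolerance = 1e-12)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, 2.5 * f1$intercept, tolerance = 1e-12)
  expect_equal(f2$resid_scale, 2.5 * f1$resid_scale, tolerance = 1e-12)
})

test_that("Fisher-z and bootstrap CIs bracket r", {
  set.seed(8)
  truth <- meta_truth(n_trials = 12, trial_corr = 0.9, seed = 77)
  ros <- draw_trial_effects(truth)
  eff <- toy_effects(ros$true_loghr_dfs, ros$true_loghr_os,
                     n = ros$n_control + ros$n_experimental)
  fit <- fit_trial_regression(eff$dfs, eff$os)
  expect_true(fit$r_ci[1] <= fit$r && fit$r <= fit$r_ci[2])
  bci <- bootstrap_r_ci(eff$dfs, eff$os, n_bootstrap = 500, seed = 2)
  expect_true(bci[1] <= fit$r && fit$r <= bci[2])
})

test_that("correlation grading follows the five-level convention", {
  expect_identical(grade_correlation(0.988), "excellent")
  expect_identical(grade_correlation(0.815), "very good")
  expect_identical(grade_correlation(0.9), "very good")    # boundary: not above 0.9
  expect_identical(grade_correlation(0.6), "good")
  expect_identical(grade_correlation(0.3), "moderate")
  expect_identical(grade_correlation(0.25), "poor")        # at the poor boundary
  expect_identical(grade_correlation(-0.95), "excellent")  # graded on |value|
  expect_error(grade_correlation(1.2), "<= 1")
})
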