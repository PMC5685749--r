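test_that("direct CI inversion gives the closed-form log-HR and variance", {
  e1 <- loghr_from_hr_ci(1.0, 0.5, 2.0, n_total = 100)
  expect_equal(e1$loghr, 0)
  expect_equal(e1$var_loghr, (log(4) / (2 * 1.959964))^2, tolerance = 1e-10)
  expect_identical(e1$method, "direct_ci")

  # same CI width on the log scale, shifted
  e2 <- loghr_from_hr_ci(0.5, 0.25, 1.0, n_total = 100)
  expect_equal(e2$loghr, log(0.5))
  expect_equal(e2$var_loghr, e1$var_loghr)

  # round trip: the reconstructed effect reproduces the input CI
  for (hr in c(0.4, 0.8, 1.3)) {
    e <- loghr_from_hr_ci(hr, hr * 0.6, hr / 0.6, n_total = 50)
    ci <- exp(e$loghr + c(-1, 1) * 1.959964 * sqrt(e$var_loghr))
    expect_equal(ci, c(hr * 0.6, hr / 0.6), tolerance = 1e-4)
  }

  expect_error(loghr_from_hr_ci(0.5, 0.6, 1.0, 100, trial_id = "X"), "X")
})

test_that("p-value route matches the closed-form O-E reconstruction", {
  # null p-value: null effect
  e0 <- loghr_from_pvalue(1, 40, 50, 50)
  expect_equal(e0$loghr, 0)

  # balanced arms, 100 events, p = 0.05: V = 25, loghr = -z * 5 / 25
  e <- loghr_from_pvalue(0.05, 100, 100, 100, direction = "favors_exp")
  expect_equal(e$var_loghr, 1 / 25)
  expect_equal(e$loghr, -qnorm(0.975) * sqrt(25) / 25, tolerance = 1e-10)
  expect_equal(e$loghr, -0.392, tolerance = 1e-3)

  # direction flips the sign only
  eh <- loghr_from_pvalue(0.05, 100, 100, 100, direction = "favors_ctl")
  expect_equal(eh$loghr, -e$loghr)
  expect_equal(eh$var_loghr, e$var_loghr)

  expect_error(loghr_from_pvalue(0, 10, 20, 20), "p = 0")
})

test_that("p-value route agrees with the Cox estimate on simulated data", {
  pat <- sim_one_trial(loghr_dfs = -0.4, loghr_os = -0.4, n_per_arm = 600,
                       censor_window = c(40, 150), seed = 21)
  z <- as.integer(pat$arm == "experimental")
  lr <- survival::survdiff(survival::Surv(os_time, os_event) ~ z, data = pat)
  p <- 1 - pchisq(lr$chisq, 1)
  events <- sum(pat$os_event)
  expect_gte(events, 500)
  cox <- cox_loghr(pat, "OS")
  e <- loghr_from_pvalue(p, events, sum(z), sum(1 - z),
                         direction = if (cox["loghr"] < 0) "favors_exp" else "favors_ctl")
  expect_lt(abs(e$loghr - cox["loghr"]), 0.05)
})

test_that("KM reconstruction is null for identical curves and tracks the Cox oracle", {
  grid <- seq(0, 60, by = 2)
  surv <- exp(-0.02 * grid)
  ctl <- km_curve("T", "control", "OS", grid, surv, n_enrolled = 100)
  exc <- km_curve("T", "experimental", "OS", grid, surv, n_enrolled = 100)
  e0 <- loghr_from_km(ctl, exc)
  expect_equal(e0$loghr, 0, tolerance = 1e-10)
  expect_identical(e0$method, "km_curves")

  # simulated trial, ~30% censoring, curves sampled every 2 months
  pat <- sim_one_trial(loghr_dfs = -0.5, loghr_os = -0.5, n_per_arm = 300,
                       h_death = 0.03, censor_window = c(10, 80), seed = 13)
  cens_frac <- 1 - mean(pat$os_event)
  expect_lt(abs(cens_frac - 0.3), 0.15)
  grid <- seq(0, min(tapply(pat$os_time, pat$arm, max)), by = 2)
  km <- loghr_from_km(degrade_to_km(pat, "OS", "control", grid),
                      degrade_to_km(pat, "OS", "experimental", grid))
  cox <- cox_loghr(pat, "OS")
  expect_lt(abs(km$loghr - cox["loghr"]), 0.07)
  # variance within a factor of 2 of the Cox variance
  expect_lt(km$var_loghr / cox["var"], 2)
  expect_gt(km$var_loghr / cox["var"], 0.5)
})

test_that("constant-censoring fallback works without an at-risk table", {
  pat <- sim_one_trial(loghr_dfs = -0.5, loghr_os = -0.5, n_per_arm = 300,
                       h_death = 0.03, censor_window = c(10, 80), seed = 17)
  grid <- seq(0, min(tapply(pat$os_time, pat$arm, max)), by = 2)
  strip <- function(cv) { cv$n_at_risk <- NULL; cv }
  km <- loghr_from_km(strip(degrade_to_km(pat, "OS", "control", grid)),
                      strip(degrade_to_km(pat, "OS", "experimental", grid)),
                      followup = c(10, 80))
  cox <- cox_loghr(pat, "OS")
  expect_lt(abs(km$loghr - cox["loghr"]), 0.15)
})

test_that("all three extraction routes are antisymmetric under arm swap", {
  # direct CI: swap means inverting the HR and its CI
  a <- loghr_from_hr_ci(0.6, 0.4, 0.9, 120)
  b <- loghr_from_hr_ci(1 / 0.6, 1 / 0.9, 1 / 0.4, 120)
  expect_equal(b$loghr, -a$loghr, tolerance = 1e-12)
  expect_equal(b$var_loghr, a$var_loghr, tolerance = 1e-12)

  # p-value route: swap flips the favoured arm
  a <- loghr_from_pvalue(0.02, 80, 60, 90, "favors_exp")
  b <- loghr_from_pvalue(0.02, 80, 90, 60, "favors_ctl")
  expect_equal(b$loghr, -a$loghr)
  expect_equal(b$var_loghr, a$var_loghr)

  # KM route: swap the curves
  pat <- sim_one_trial(loghr_dfs = -0.4, loghr_os = -0.4, n_per_arm = 200, seed = 5)
  grid <- seq(0, min(tapply(pat$os_time, pat$arm, max)), by = 3)
  c1 <- degrade_to_km(pat, "OS", "control", grid)
  c2 <- degrade_to_km(pat, "OS", "experimental", grid)
  ab <- loghr_from_km(c1, c2)
  ba <- loghr_from_km(c2, c1)
  expect_equal(ba$loghr, -ab$loghr, tolerance = 1e-10)
  expect_equal(ba$var_loghr, ab$var_loghr, tolerance = 1e-10)
})

test_that("denser curve grids move the KM estimate toward the Cox oracle", {
  errs <- sapply(1:40, function(s) {
    pat <- sim_one_trial(loghr_dfs = -0.5, loghr_os = -0.5, n_per_arm = 150,
                         h_death = 0.03, censor_window = c(1e5, 1e5), seed = 100 + s)
    cox <- cox_loghr(pat, "OS")["loghr"]
    tmax <- min(tapply(pat$os_time, pat$arm, max))
    err_at <- function(step) {
      grid <- seq(0, tmax, by = step)
      abs(loghr_from_km(degrade_to_km(pat, "OS", "control", grid),
                        degrade_to_km(pat, "OS", "experimental", grid))$loghr - cox)
    }
    c(coarse = unname(err_at(8)), fine = unname(err_at(4)))
  })
  expect_lte(mean(errs["fine", ]), mean(errs["coarse", ]))
})

test_that("summary-table dispatch and effect-table IO behave", {
  summ <- data.frame(trial_id = c("A", "B"), endpoint = "OS",
                     n_exp = c(50, 60), n_ctl = c(50, 55),
                     hr = c(0.7, NA), ci_lo = c(0.5, NA), ci_hi = c(0.98, NA),
                     p_value = c(NA, 0.04), events_total = c(NA, 70),
                     direction = c(NA, "favors_exp"))
  eff <- extract_effects(summ)
  expect_identical(eff$method, c("direct_ci", "pvalue_events"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_effects(eff, f)
  back <- read_effects(f)
  expect_equal(back$loghr, eff$loghr, tolerance = 1e-10)
  expect_error(extract_effects(summ[, -3]), "n_exp")
})

test_that("KM CSV round-trips through write_km/read_km", {
  pat <- sim_one_trial(n_per_arm = 50, seed = 31)
  grid <- seq(0, 48, by = 6)
  curves <- list(degrade_to_km(pat, "DFS", "control", grid),
                 degrade_to_km(pat, "DFS", "experimental", grid))
  f <- withr::local_tempfile(fileext = ".csv")
  write_km(curves, f)
  back <- read_km(f)
  expect_length(back, 2)
  orig <- curves[[1]]
  got <- back[[paste(orig$trial_id, "control", "DFS", sep = ".")]]
  expect_equal(got$survival, orig$survival, tolerance = 1e-10)
  expect_equal(got$n_at_risk, orig$n_at_risk)
})
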