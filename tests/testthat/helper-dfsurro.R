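# shared simulation helpers for the suite

# a single two-arm trial with fixed true effects, built through the
# package's generator machinery
sim_one_trial <- function(loghr_dfs = -0.5, loghr_os = -0.5,
                          n_per_arm = 300, theta = 6,
                          h_rec = 0.03, h_death = 0.015,
                          censor_window = c(12, 120), seed = 1) {
  truth <- meta_truth(n_trials = 3, mean_loghr_dfs = loghr_dfs,
                      mean_loghr_os = loghr_os,
                      sd_loghr_dfs = 0, sd_loghr_os = 0,
                      trial_corr = 0, copula_theta = theta,
                      base_hazard_rec = h_rec, base_hazard_death = h_death,
                      censor_window = censor_window,
                      arm_size_range = c(n_per_arm, n_per_arm), seed = seed)
  roster <- draw_trial_effects(truth)
  simulate_patients(roster[1, ], truth, trial_index = seed)
}

# censored bivariate pairs drawn directly from the Clayton survival model
# with exponential margins -- the data-generating model of fit_copula itself
# (no min-construction, so theta is the true dependence of the pair)
sim_bivariate <- function(n, theta, h1 = 0.03, h2 = 0.015,
                          censor_window = c(60, 250), seed = 1) {
  set.seed(seed)
  uv <- rclayton(n, theta)
  t1 <- -log(uv[, 1]) / h1
  t2 <- -log(uv[, 2]) / h2
  cc <- runif(n, censor_window[1], censor_window[2])
  data.frame(trial_id = "B", arm = "control",
             dfs_time = pmin(t1, cc), dfs_event = as.integer(t1 <= cc),
             os_time = pmin(t2, cc), os_event = as.integer(t2 <= cc))
}

# Cox partial-likelihood oracle for the treatment log-HR of one trial
cox_loghr <- function(pat, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  t <- if (endpoint == "DFS") pat$dfs_time else pat$os_time
  e <- if (endpoint == "DFS") pat$dfs_event else pat$os_event
  z <- as.integer(pat$arm == "experimental")
  fit <- survival::coxph(survival::Surv(t, e) ~ z)
  c(loghr = unname(stats::coef(fit)), var = unname(stats::vcov(fit)[1, 1]))
}

# matched per-trial effect tables with controlled trial-level structure,
# built directly on the log-HR scale (no patient simulation)
toy_effects <- function(x, y, n = rep(100L, length(x)),
                        var = rep(0.04, length(x))) {
  ids <- sprintf("T%02d", seq_along(x))
  list(dfs = data.frame(trial_id = ids, endpoint = "DFS", loghr = x,
                        var_loghr = var, n_total = n, method = "direct_ci",
                        stringsAsFactors = FALSE),
       os = data.frame(trial_id = ids, endpoint = "OS", loghr = y,
                       var_loghr = var, n_total = n, method = "direct_ci",
                       stringsAsFactors = FALSE))
}

# per-trial observed effects for a whole synthetic meta-analysis, using the
# Cox oracle on the simulated records (fast route for calibration studies)
meta_effects_cox <- function(truth) {
  sim <- simulate_meta_analysis(truth)
  rows <- lapply(split(sim$patients, sim$patients$trial_id), function(p) {
    cd <- cox_loghr(p, "DFS"); co <- cox_loghr(p, "OS")
    data.frame(trial_id = p$trial_id[1], n_total = nrow(p),
               dfs = cd["loghr"], var_dfs = cd["var"],
               os = co["loghr"], var_os = co["var"],
               stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, rows)
  list(roster = sim$roster,
       dfs = data.frame(trial_id = eff$trial_id, endpoint = "DFS",
                        loghr = eff$dfs, var_loghr = eff$var_dfs,
                        n_total = eff$n_total, method = "cox_oracle"),
       os = data.frame(trial_id = eff$trial_id, endpoint = "OS",
                       loghr = eff$os, var_loghr = eff$var_os,
                       n_total = eff$n_total, method = "cox_oracle"))
}
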