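#' Ground-truth parameters for a synthetic surrogacy meta-analysis
#'
#' Bundles everything the generator needs: the bivariate-normal distribution
#' of true per-trial treatment effects (log hazard ratios on the
#' disease-free-survival and overall-survival endpoints, with a trial-level
#' correlation), the Clayton dependence between each patient's latent
#' recurrence and death times, exponential baseline hazards, the uniform
#' censoring window, and the range of arm sizes. Defaults emulate a
#' meta-analysis of adjuvant-therapy trials after curative treatment for
#' hepatocellular carcinoma: around ten trials of 30--150 patients per arm,
#' moderately protective treatment effects, strong within-patient dependence
#' between recurrence and death, and administrative censoring spread over a
#' 1--10 year follow-up window.
#'
#' @param n_trials number of trials (>= 3; the trial-level regression needs
#'   at least three points).
#' @param mean_loghr_dfs,mean_loghr_os means of the true per-trial log hazard
#'   ratios (experimental vs control; negative favours experimental).
#' @param sd_loghr_dfs,sd_loghr_os between-trial standard deviations (>= 0).
#' @param trial_corr true trial-level correlation of the two effects,
#'   in \[-1, 1\].
#' @param copula_theta Clayton copula parameter (> 0) linking each patient's
#'   latent recurrence and death times; Kendall's tau = theta / (theta + 2).
#' @param base_hazard_rec,base_hazard_death control-arm exponential hazards
#'   (events per month, > 0) for recurrence and death.
#' @param censor_window two non-decreasing non-negative months; censoring
#'   times are uniform on this window and shared by both endpoints
#'   (one follow-up clock per patient).
#' @param arm_size_range two counts (lo <= hi); per-arm sample sizes are
#'   uniform on this range.
#' @param seed integer seed governing the whole meta-analysis; per-trial
#'   substreams are derived deterministically from (seed, trial index).
#' @return an object of class `meta_truth`.
#' @examples
#' truth <- meta_truth(n_trials = 5, seed = 42)
#' rosters <- draw_trial_effects(truth)
#' @export
meta_truth <- function(n_trials = 10L,
                       mean_loghr_dfs = -0.5,
                       mean_loghr_os = -0.35,
                       sd_loghr_dfs = 0.40,
                       sd_loghr_os = 0.30,
                       trial_corr = 0.85,
                       copula_theta = 6,
                       base_hazard_rec = 0.030,
                       base_hazard_death = 0.015,
                       censor_window = c(12, 120),
                       arm_size_range = c(30L, 150L),
                       seed = 1L) {
  truth <- structure(
    list(n_trials = as.integer(n_trials),
         mean_loghr_dfs = mean_loghr_dfs, mean_loghr_os = mean_loghr_os,
         sd_loghr_dfs = sd_loghr_dfs, sd_loghr_os = sd_loghr_os,
         trial_corr = trial_corr, copula_theta = copula_theta,
         base_hazard_rec = base_hazard_rec,
         base_hazard_death = base_hazard_death,
         censor_window = as.numeric(censor_window),
         arm_size_range = as.integer(arm_size_range),
         seed = as.integer(seed)),
    class = "meta_truth")
  validate_meta_truth(truth)
  truth
}

validate_meta_truth <- function(truth) {
  check_scalar_num(truth$n_trials, "n_trials", lo = 3)
  check_scalar_num(truth$mean_loghr_dfs, "mean_loghr_dfs")
  check_scalar_num(truth$mean_loghr_os, "mean_loghr_os")
  check_scalar_num(truth$sd_loghr_dfs, "sd_loghr_dfs", lo = 0)
  check_scalar_num(truth$sd_loghr_os, "sd_loghr_os", lo = 0)
  check_scalar_num(truth$trial_corr, "trial_corr", lo = -1, hi = 1)
  check_scalar_num(truth$copula_theta, "copula_theta", lo = 0, strict_lo = TRUE)
  check_scalar_num(truth$base_hazard_rec, "base_hazard_rec", lo = 0, strict_lo = TRUE)
  check_scalar_num(truth$base_hazard_death, "base_hazard_death", lo = 0, strict_lo = TRUE)
  if (length(truth$censor_window) != 2L || any(truth$censor_window < 0) ||
      truth$censor_window[1] > truth$censor_window[2])
    stop_input("'censor_window' must be two non-negative months with lo <= hi")
  if (length(truth$arm_size_range) != 2L || any(truth$arm_size_range < 1L) ||
      truth$arm_size_range[1] > truth$arm_size_range[2])
    stop_input("'arm_size_range' must be two counts >= 1 with lo <= hi")
  check_scalar_num(truth$seed, "seed")
  invisible(truth)
}

#' Draw per-trial true treatment effects and arm sizes
#'
#' The (log-HR DFS, log-HR OS) pairs come from a bivariate normal with the
#' means, standard deviations and trial-level correlation stored in `truth`;
#' arm sizes are uniform on `arm_size_range`. Reproducible from `truth$seed`.
#'
#' @param truth a [meta_truth()] object.
#' @return a data frame (the trial roster) with columns `trial_id`,
#'   `n_control`, `n_experimental`, `true_loghr_dfs`, `true_loghr_os`.
#' @export
draw_trial_effects <- function(truth) {
  validate_meta_truth(truth)
  with_seed(truth$seed, {
    J <- truth$n_trials
    z1 <- stats::rnorm(J)
    z2 <- stats::rnorm(J)
    r <- truth$trial_corr
    b_dfs <- truth$mean_loghr_dfs + truth$sd_loghr_dfs * z1
    b_os <- truth$mean_loghr_os +
      truth$sd_loghr_os * (r * z1 + sqrt(max(0, 1 - r^2)) * z2)
    lo <- truth$arm_size_range[1]; hi <- truth$arm_size_range[2]
    n_ctl <- lo + floor(stats::runif(J) * (hi - lo + 1L))
    n_exp <- lo + floor(stats::runif(J) * (hi - lo + 1L))
    data.frame(trial_id = sprintf("T%02d", seq_len(J)),
               n_control = as.integer(pmin(n_ctl, hi)),
               n_experimental = as.integer(pmin(n_exp, hi)),
               true_loghr_dfs = b_dfs, true_loghr_os = b_os,
               stringsAsFactors = FALSE)
  })
}

#' Sample from a Clayton copula
#'
#' Conditional-distribution method; `theta = 0` gives independent uniforms.
#'
#' @param n number of pairs.
#' @param theta Clayton parameter (>= 0).
#' @return an `n` x 2 matrix of uniforms with Clayton dependence.
#' @export
rclayton <- function(n, theta) {
  check_scalar_num(theta, "theta", lo = 0)
  u <- stats::runif(n)
  if (theta < 1e-12) return(cbind(u, stats::runif(n)))
  w <- stats::runif(n)
  v <- (u^(-theta) * (w^(-theta / (1 + theta)) - 1) + 1)^(-1 / theta)
  cbind(u, v)
}

#' Simulate patient-level records for one trial
#'
#' For each patient a Clayton-dependent uniform pair drives the latent
#' recurrence and death times (exponential margins with proportional-hazards
#' treatment effects on the trial's true log-HRs); disease-free survival is
#' the time to the first of recurrence or death, overall survival the time to
#' death, and a single uniform censoring time truncates both endpoints, so
#' `os_time >= dfs_time` holds by construction.
#'
#' @param roster one row of the data frame from [draw_trial_effects()].
#' @param truth the [meta_truth()] the roster was drawn from.
#' @param trial_index integer used with `truth$seed` to derive the trial's
#'   random substream (defaults to the numeric suffix of `trial_id`).
#' @return a data frame of patient records with columns `trial_id`, `arm`
#'   (`"control"`/`"experimental"`), `dfs_time`, `dfs_event`, `os_time`,
#'   `os_event` (events coded 1 = event, 0 = censored).
#' @export
simulate_patients <- function(roster, truth, trial_index = NULL) {
  validate_meta_truth(truth)
  if (!all(c("trial_id", "n_control", "n_experimental",
             "true_loghr_dfs", "true_loghr_os") %in% names(roster)))
    stop_input("'roster' must be a row of draw_trial_effects() output")
  if (is.null(trial_index)) {
    trial_index <- suppressWarnings(as.integer(gsub("\\D", "", roster$trial_id[1])))
    if (is.na(trial_index))
      trial_index <- sum(utf8ToInt(as.character(roster$trial_id[1])))
  }
  with_seed(substream_seed(truth$seed, trial_index), {
    n_ctl <- roster$n_control[1]; n_exp <- roster$n_experimental[1]
    n <- n_ctl + n_exp
    z <- c(rep(0L, n_ctl), rep(1L, n_exp))
    uv <- rclayton(n, truth$copula_theta)
    rec <- -log(uv[, 1]) / (truth$base_hazard_rec * exp(roster$true_loghr_dfs[1] * z))
    death <- -log(uv[, 2]) / (truth$base_hazard_death * exp(roster$true_loghr_os[1] * z))
    dfs <- pmin(rec, death)
    cens <- stats::runif(n, truth$censor_window[1], truth$censor_window[2])
    data.frame(trial_id = roster$trial_id[1],
               arm = ifelse(z == 1L, "experimental", "control"),
               dfs_time = pmin(dfs, cens),
               dfs_event = as.integer(dfs <= cens),
               os_time = pmin(death, cens),
               os_event = as.integer(death <= cens),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic meta-analysis
#'
#' @param truth a [meta_truth()] object.
#' @return a list with the trial `roster` (see [draw_trial_effects()]) and
#'   the pooled `patients` data frame across all trials.
#' @export
simulate_meta_analysis <- function(truth) {
  roster <- draw_trial_effects(truth)
  patients <- do.call(rbind, lapply(seq_len(nrow(roster)), function(j)
    simulate_patients(roster[j, ], truth, trial_index = j)))
  rownames(patients) <- NULL
  list(roster = roster, patients = patients)
}

#' Degrade patient records to a digitized Kaplan-Meier curve
#'
#' Evaluates the product-limit estimate for one arm and one endpoint on a
#' time grid, with the number at risk at each grid point — the shape of
#' information a published trial report provides.
#'
#' @param records patient data frame as produced by [simulate_patients()].
#' @param endpoint `"DFS"` or `"OS"`.
#' @param arm `"control"` or `"experimental"`.
#' @param grid strictly increasing times (months, >= 0); 0 is prepended when
#'   absent so the curve starts at survival 1.
#' @return a [km_curve()] object.
#' @export
degrade_to_km <- function(records, endpoint = c("DFS", "OS"),
                          arm = c("control", "experimental"), grid) {
  endpoint <- match.arg(endpoint)
  arm <- match.arg(arm)
  sub <- records[records$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_input("no records for arm '%s'", arm)
  if (any(diff(grid) <= 0) || any(grid < 0))
    stop_input("'grid' must be strictly increasing and start >= 0")
  if (grid[1] > 0) grid <- c(0, grid)
  time <- if (endpoint == "DFS") sub$dfs_time else sub$os_time
  event <- if (endpoint == "DFS") sub$dfs_event else sub$os_event
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  sm <- summary(fit, times = grid, extend = TRUE)
  km_curve(trial_id = sub$trial_id[1], arm = arm, endpoint = endpoint,
           times = grid, survival = sm$surv, n_at_risk = sm$n.risk,
           n_enrolled = nrow(sub))
}

#' Write / read patient records as CSV
#'
#' Columns: `trial_id, arm, dfs_time, dfs_event, os_time, os_event`
#' (events coded 1 = event, 0 = censored).
#'
#' @param patients patient data frame.
#' @param path file path.
#' @return `read_patients` returns the validated data frame.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients[, c("trial_id", "arm", "dfs_time", "dfs_event",
                                "os_time", "os_event")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  pat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "arm", "dfs_time", "dfs_event", "os_time", "os_event")
  miss <- setdiff(need, names(pat))
  if (length(miss))
    stop_input("patient CSV is missing column(s): %s", paste(miss, collapse = ", "))
  validate_patients(pat)
  pat
}

#' Check the structural invariants of patient records
#'
#' Overall survival can never precede disease-free survival, and a death
#' observed at the DFS time must itself be a DFS event.
#'
#' @param patients patient data frame.
#' @return the data frame, invisibly; errors on violation.
#' @export
validate_patients <- function(patients) {
  if (any(patients$os_time < patients$dfs_time - 1e-12))
    stop_input("invariant violated: os_time < dfs_time in %d record(s)",
               sum(patients$os_time < patients$dfs_time - 1e-12))
  bad <- patients$os_event == 1L &
    abs(patients$os_time - patients$dfs_time) < 1e-12 &
    patients$dfs_event != 1L
  if (any(bad))
    stop_input("invariant violated: death at the DFS time not flagged as a DFS event (%d record(s))",
               sum(bad))
  if (!all(patients$dfs_event %in% c(0L, 1L)) || !all(patients$os_event %in% c(0L, 1L)))
    stop_input("event flags must be coded 0/1")
  invisible(patients)
}
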