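#' Path to a packaged trial-roster fixture
#'
#' Two transcribed trial rosters ship with the package: the seven trials
#' comparing radiofrequency ablation plus transarterial chemoembolization
#' with ablation alone (`"table2_rfa_tace.csv"`) and the ten trials comparing
#' curative treatment plus interferon with curative treatment alone
#' (`"table3_ct_ifn.csv"`).
#'
#' @param name fixture file name.
#' @return absolute path to the installed fixture.
#' @export
dfsurro_fixture <- function(name = c("table2_rfa_tace.csv", "table3_ct_ifn.csv")) {
  name <- match.arg(name)
  system.file("extdata", name, package = "dfsurro", mustWork = TRUE)
}

#' Read, validate, and write trial-roster tables
#'
#' Columns: `comparison, year, author, design, n_exp, n_ctl, n_total,
#' followup_lo, followup_hi`. Validation enforces
#' `n_total = n_exp + n_ctl` whenever both arms are present and
#' `followup_lo <= followup_hi`; violations are reported with the offending
#' row numbers.
#'
#' @param path CSV path.
#' @return `read_trial_roster` returns the validated data frame.
#' @export
read_trial_roster <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_roster(rows)
  rows
}

#' @rdname read_trial_roster
#' @param rows roster data frame.
#' @export
validate_roster <- function(rows) {
  need <- c("comparison", "year", "author", "design",
            "n_exp", "n_ctl", "n_total", "followup_lo", "followup_hi")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop_input("roster is missing column(s): %s", paste(miss, collapse = ", "))
  both <- is.finite(rows$n_exp) & is.finite(rows$n_ctl)
  bad_sum <- which(both & rows$n_exp + rows$n_ctl != rows$n_total)
  bad_fu <- which(rows$followup_lo > rows$followup_hi)
  if (length(bad_sum) || length(bad_fu))
    stop_input("roster validation failed: %s%s",
               if (length(bad_sum)) sprintf("n_exp + n_ctl != n_total in row(s) %s; ",
                                            paste(bad_sum, collapse = ", ")) else "",
               if (length(bad_fu)) sprintf("followup_lo > followup_hi in row(s) %s",
                                           paste(bad_fu, collapse = ", ")) else "")
  invisible(rows)
}

#' @rdname read_trial_roster
#' @export
write_trial_roster <- function(rows, path) {
  validate_roster(rows)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inclusion bookkeeping: trials and patients per comparison
#'
#' Counts trials and sums total patients within each comparison and overall.
#'
#' @param rows a validated roster data frame (possibly several rosters bound
#'   together).
#' @return a data frame with columns `comparison`, `n_trials`, `n_patients`;
#'   the last row (`comparison = "overall"`) holds the totals.
#' @export
tabulate_inclusion <- function(rows) {
  validate_roster(rows)
  per <- do.call(rbind, lapply(split(rows, rows$comparison), function(g)
    data.frame(comparison = g$comparison[1], n_trials = nrow(g),
               n_patients = sum(g$n_total), stringsAsFactors = FALSE)))
  per <- per[order(per$comparison), ]
  out <- rbind(per, data.frame(comparison = "overall", n_trials = nrow(rows),
                               n_patients = sum(rows$n_total)))
  rownames(out) <- NULL
  out
}

#' Default analysis configuration
#'
#' All tunables of the end-to-end pipeline in one list: the seed, the
#' synthetic-generator parameters (see [meta_truth()]), the copula family
#' (Clayton is the one implemented), the trial-level weighting scheme, the
#' bootstrap size, the Kaplan-Meier degradation grid step (months), and
#' output options.
#'
#' @param seed integer seed governing every stochastic stage.
#' @return a named list, suitable for [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       truth = list(),              # overrides for meta_truth()
       copula_family = "clayton",
       weights_scheme = "n_total",
       n_bootstrap = 200L,
       km_grid_step = 3,
       inputs = NULL,               # or list(effects_csv=, patients_csv=)
       out_dir = NULL,
       make_plots = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file.
#' @param seed fallback seed when the file does not set one.
#' @export
read_config <- function(path, seed = 1L) {
  cfg <- default_config(seed)
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  if (!identical(config$copula_family, "clayton"))
    stop_input("copula_family '%s' is not supported (implemented: clayton)",
               config$copula_family)
  if (!config$weights_scheme %in% c("n_total", "inverse_variance", "equal"))
    stop_input("unknown weights_scheme '%s'", config$weights_scheme)
  check_scalar_num(config$seed, "seed")
  check_scalar_num(config$n_bootstrap, "n_bootstrap", lo = 200)
  check_scalar_num(config$km_grid_step, "km_grid_step", lo = 0, strict_lo = TRUE)
  invisible(config)
}

# reconstruct per-trial effects from IPD via the published-report path:
# degrade each arm/endpoint to a gridded KM curve, then pool interval
# log-rank contributions
effects_from_patients <- function(patients, km_grid_step, t_max) {
  out <- list()
  for (id in unique(patients$trial_id)) {
    rec <- patients[patients$trial_id == id, ]
    for (ep in c("DFS", "OS")) {
      # grid stops where the shorter arm runs out of follow-up for this
      # endpoint, so no interval starts with an empty risk set
      t_ep <- if (ep == "DFS") rec$dfs_time else rec$os_time
      t_hi <- min(t_max,
                  max(t_ep[rec$arm == "control"]),
                  max(t_ep[rec$arm == "experimental"]))
      grid <- seq(0, t_hi, by = km_grid_step)
      ctl <- degrade_to_km(rec, ep, "control", grid)
      exc <- degrade_to_km(rec, ep, "experimental", grid)
      out[[length(out) + 1L]] <- loghr_from_km(ctl, exc)
    }
  }
  eff <- do.call(rbind, out)
  list(dfs = eff[eff$endpoint == "DFS", ], os = eff[eff$endpoint == "OS", ])
}

#' Run the full surrogacy pipeline
#'
#' Orchestrates every stage end to end: input acquisition (either the
#' synthetic meta-analysis generator or user CSVs), effect reconstruction,
#' individual-level copula surrogacy (when patient-level records exist),
#' trial-level regression with grading, the surrogate threshold effect, and
#' leave-one-out cross-validation. All randomness derives from
#' `config$seed`, so a repeated run produces a byte-identical JSON report.
#'
#' @param config a list from [default_config()] or [read_config()].
#' @return a list of class `surrogacy_report` with elements `meta` (seed,
#'   package version, configuration echo), `individual`, `trial` (regression,
#'   grades, STE), `cv`, and `inputs` (provenance of each stage's input);
#'   when `config$out_dir` is set, the report JSON and all stage CSVs (plus
#'   plots when `config$make_plots`) are written there.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  patients <- NULL; roster <- NULL; truth <- NULL
  if (is.null(config$inputs)) {
    truth <- do.call(meta_truth, c(config$truth,
                                   list(seed = config$seed)[!("seed" %in% names(config$truth))]))
    sim <- simulate_meta_analysis(truth)
    patients <- sim$patients; roster <- sim$roster
    eff <- effects_from_patients(patients, config$km_grid_step,
                                 t_max = truth$censor_window[2])
    provenance <- "synthetic"
  } else {
    if (!is.null(config$inputs$patients_csv))
      patients <- read_patients(config$inputs$patients_csv)
    if (!is.null(config$inputs$effects_csv)) {
      e <- read_effects(config$inputs$effects_csv)
      eff <- list(dfs = e[e$endpoint == "DFS", ], os = e[e$endpoint == "OS", ])
    } else if (!is.null(patients)) {
      eff <- effects_from_patients(patients, config$km_grid_step,
                                   t_max = max(patients$os_time))
    } else {
      stop_input("inputs must provide effects_csv and/or patients_csv")
    }
    provenance <- "user_csv"
  }

  individual <- NULL
  if (!is.null(patients)) {
    validate_patients(patients)
    ind <- individual_surrogacy(patients, n_bootstrap = config$n_bootstrap,
                                seed = substream_seed(config$seed, 9001L))
    individual <- list(rho = ind$rho, rho_ci = as.numeric(ind$rho_ci),
                       rho_grade = grade_correlation(ind$rho),
                       tau = ind$tau, theta_hat = ind$theta_hat,
                       n_patients = ind$n_patients,
                       n_bootstrap = ind$n_bootstrap,
                       diagnostics = ind$diagnostics)
  }

  fit <- fit_trial_regression(eff$dfs, eff$os, config$weights_scheme)
  ste <- compute_ste(fit)
  cv <- loocv(eff$dfs, eff$os, config$weights_scheme)

  report <- structure(list(
    meta = list(package = "dfsurro",
                version = as.character(utils::packageVersion("dfsurro")),
                seed = config$seed,
                copula_family = config$copula_family,
                weights_scheme = config$weights_scheme,
                input_provenance = provenance),
    individual = individual,
    trial = list(slope = fit$slope, intercept = fit$intercept,
                 resid_scale = fit$resid_scale, r = fit$r,
                 r_ci = as.numeric(fit$r_ci),
                 r_grade = grade_correlation(fit$r),
                 n_trials = fit$n_trials,
                 ste_beneficial = ste$ste_beneficial,
                 ste_harmful = ste$ste_harmful,
                 ste_beneficial_2dp = round(ste$ste_beneficial, 2),
                 ste_harmful_2dp = round(ste$ste_harmful, 2)),
    cv = list(n_trials = cv$summary$n_trials, n_inside = cv$summary$n_inside,
              coverage = cv$summary$coverage,
              records = cv$records)),
    class = "surrogacy_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(config$out_dir, "report.json"))
    write_effects(rbind(eff$dfs, eff$os), file.path(config$out_dir, "effects.csv"))
    write_loocv(cv, file.path(config$out_dir, "loocv.csv"))
    if (!is.null(patients))
      write_patients(patients, file.path(config$out_dir, "patients.csv"))
    if (!is.null(individual))
      write_individual_result(ind, file.path(config$out_dir, "individual.csv"),
                              file.path(config$out_dir, "individual_diagnostics.json"))
    if (isTRUE(config$make_plots)) {
      ggplot2::ggsave(file.path(config$out_dir, "trial_regression.png"),
                      plot_trial_regression(fit), width = 6, height = 5, dpi = 150)
      ggplot2::ggsave(file.path(config$out_dir, "loocv_forest.png"),
                      plot_loocv(cv), width = 6, height = 5, dpi = 150)
    }
  }
  report
}

#' Serialize a pipeline report as JSON
#'
#' Deterministic formatting (fixed precision, no timestamps), so identical
#' seeds yield byte-identical files.
#'
#' @param report a [run_pipeline()] result.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                          pretty = TRUE, na = "null")
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.surrogacy_report <- function(x, ...) {
  cat(sprintf("Surrogacy pipeline report (seed %d, %s inputs)\n",
              x$meta$seed, x$meta$input_provenance))
  if (!is.null(x$individual))
    cat(sprintf("  individual level: rho = %.3f (95%% CI %.3f-%.3f) [%s]\n",
                x$individual$rho, x$individual$rho_ci[1], x$individual$rho_ci[2],
                x$individual$rho_grade))
  cat(sprintf("  trial level: R = %.3f (95%% CI %.3f-%.3f) [%s], slope %.3f\n",
              x$trial$r, x$trial$r_ci[1], x$trial$r_ci[2], x$trial$r_grade,
              x$trial$slope))
  cat(sprintf("  STE: HR(DFS) %.2f (beneficial) / %.2f (harmful)\n",
              x$trial$ste_beneficial, x$trial$ste_harmful))
  cat(sprintf("  LOOCV: %d of %d observed OS effects inside the 95%% prediction interval\n",
              x$cv$n_inside, x$cv$n_trials))
  invisible(x)
}
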