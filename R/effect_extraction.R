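#' A digitized Kaplan-Meier curve for one arm and one endpoint
#'
#' The information a published report carries: survival probabilities read
#' off a printed product-limit curve on a time grid, optionally with the
#' number-at-risk table, plus the number of patients enrolled in the arm.
#'
#' @param trial_id trial identifier.
#' @param arm `"control"` or `"experimental"`.
#' @param endpoint `"DFS"` or `"OS"`.
#' @param times strictly increasing months starting at 0.
#' @param survival probabilities in \[0, 1\], non-increasing, starting at 1.
#' @param n_at_risk optional non-increasing at-risk counts (one per grid
#'   point); `NULL` when the report printed no at-risk table.
#' @param n_enrolled number of patients enrolled in the arm.
#' @return an object of class `km_curve`.
#' @export
km_curve <- function(trial_id, arm, endpoint, times, survival,
                     n_at_risk = NULL, n_enrolled) {
  arm <- match.arg(arm, c("control", "experimental"))
  endpoint <- match.arg(endpoint, c("DFS", "OS"))
  if (length(times) != length(survival))
    stop_input("times and survival must have equal length (trial %s)", trial_id)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop_input("times must be strictly increasing and start at 0 (trial %s)", trial_id)
  if (abs(survival[1] - 1) > 1e-9 || any(survival < -1e-9) || any(survival > 1 + 1e-9) ||
      any(diff(survival) > 1e-9))
    stop_input("survival must start at 1 and be non-increasing in [0, 1] (trial %s)", trial_id)
  if (!is.null(n_at_risk)) {
    if (length(n_at_risk) != length(times))
      stop_input("n_at_risk must match the time grid (trial %s)", trial_id)
    if (any(n_at_risk < 0) || any(diff(n_at_risk) > 1e-9))
      stop_input("n_at_risk must be non-negative and non-increasing (trial %s)", trial_id)
    if (n_at_risk[1] > n_enrolled + 1e-9)
      stop_input("n_at_risk[1] exceeds n_enrolled (trial %s)", trial_id)
  }
  structure(list(trial_id = as.character(trial_id), arm = arm,
                 endpoint = endpoint, times = as.numeric(times),
                 survival = pmin(pmax(as.numeric(survival), 0), 1),
                 n_at_risk = if (is.null(n_at_risk)) NULL else as.numeric(n_at_risk),
                 n_enrolled = as.integer(n_enrolled)),
            class = "km_curve")
}

# one reconstructed treatment effect: log hazard ratio (experimental vs
# control, negative favours experimental) with its variance and provenance
trial_effect <- function(trial_id, endpoint, loghr, var_loghr, n_total, method) {
  if (!is.finite(var_loghr) || var_loghr <= 0)
    stop_input("var_loghr must be > 0 (trial %s)", trial_id)
  if (n_total < 2) stop_input("n_total must be >= 2 (trial %s)", trial_id)
  data.frame(trial_id = as.character(trial_id), endpoint = endpoint,
             loghr = loghr, var_loghr = var_loghr,
             n_total = as.integer(n_total), method = method,
             stringsAsFactors = FALSE)
}

#' Log hazard ratio from a reported HR and its 95\% confidence interval
#'
#' `loghr = log(hr)`; the variance comes from the CI width on the log scale,
#' `var = ((log(ci_hi) - log(ci_lo)) / (2 * 1.959964))^2`.
#'
#' @param hr reported hazard ratio (experimental vs control, > 0).
#' @param ci_lo,ci_hi 95\% confidence limits on the HR scale,
#'   `0 < ci_lo <= hr <= ci_hi`.
#' @param n_total total patients in the trial.
#' @param trial_id trial identifier.
#' @param endpoint `"DFS"` or `"OS"`.
#' @return a one-row trial-effect data frame (`method = "direct_ci"`).
#' @examples
#' loghr_from_hr_ci(0.5, 0.25, 1.0, n_total = 200, trial_id = "A", endpoint = "OS")
#' @export
loghr_from_hr_ci <- function(hr, ci_lo, ci_hi, n_total,
                             trial_id = "trial", endpoint = "OS") {
  if (!(is.finite(hr) && is.finite(ci_lo) && is.finite(ci_hi)) ||
      ci_lo <= 0 || !(ci_lo <= hr && hr <= ci_hi))
    stop_input("trial %s: need 0 < ci_lo <= hr <= ci_hi (got %s, %s, %s)",
               trial_id, ci_lo, hr, ci_hi)
  v <- ((log(ci_hi) - log(ci_lo)) / (2 * Z975))^2
  trial_effect(trial_id, endpoint, log(hr), v, n_total, "direct_ci")
}

#' Log hazard ratio from a two-sided p-value and event counts
#'
#' The indirect route for reports that print only a log-rank p-value: with
#' `V = events_total * n_exp * n_ctl / (n_exp + n_ctl)^2` the absolute
#' observed-minus-expected statistic is `qnorm(1 - p/2) * sqrt(V)`, so
#' `loghr = +/- (O - E) / V` with `var = 1 / V`, signed by which arm the
#' report says the effect favours.
#'
#' @param p_two_sided two-sided p-value in (0, 1\]; `p = 1` yields a null
#'   log-HR, `p = 0` is unextractable.
#' @param events_total total events across arms (>= 1).
#' @param n_exp,n_ctl per-arm sample sizes.
#' @param direction `"favors_exp"` (HR < 1) or `"favors_ctl"`.
#' @param trial_id,endpoint provenance labels.
#' @return a one-row trial-effect data frame (`method = "pvalue_events"`).
#' @export
loghr_from_pvalue <- function(p_two_sided, events_total, n_exp, n_ctl,
                              direction = c("favors_exp", "favors_ctl"),
                              trial_id = "trial", endpoint = "OS") {
  direction <- match.arg(direction)
  if (!is.finite(p_two_sided) || p_two_sided <= 0 || p_two_sided > 1)
    stop_input("trial %s: p-value must lie in (0, 1]; p = 0 is unextractable", trial_id)
  if (events_total < 1) stop_input("trial %s: events_total must be >= 1", trial_id)
  V <- events_total * n_exp * n_ctl / (n_exp + n_ctl)^2
  ome <- stats::qnorm(1 - p_two_sided / 2) * sqrt(V)
  sgn <- if (direction == "favors_exp") -1 else 1
  trial_effect(trial_id, endpoint, sgn * ome / V, 1 / V, n_exp + n_ctl,
               "pvalue_events")
}

# effective numbers at risk at interval starts: from the printed at-risk
# table when available, otherwise n_enrolled scaled by survival and by a
# constant-censoring adjustment spread over the follow-up window
effective_at_risk <- function(curve, at, followup = NULL) {
  if (!is.null(curve$n_at_risk)) {
    stats::approx(curve$times, curve$n_at_risk, xout = at,
                  method = "constant", rule = 2)$y
  } else {
    if (is.null(followup)) followup <- c(0, max(curve$times))
    s_at <- stats::approx(curve$times, curve$survival, xout = at,
                          method = "constant", rule = 2)$y
    span <- max(followup[2] - followup[1], 1e-9)
    cens_frac <- pmin(pmax((at - followup[1]) / span, 0), 1)
    curve$n_enrolled * s_at * (1 - cens_frac)
  }
}

#' Log hazard ratio reconstructed from a pair of Kaplan-Meier curves
#'
#' Implements the interval-based actuarial reconstruction used when a report
#' provides survival curves but no hazard ratio. For each interval the number
#' of events per arm is back-calculated from the survival drop and the
#' effective number at risk (the printed at-risk table when available,
#' otherwise the enrolled count decremented under a constant-censoring
#' assumption over the follow-up window); per-interval log-rank
#' observed-minus-expected contributions and hypergeometric variances are
#' pooled into `loghr = sum(O - E) / sum(V)` with `var = 1 / sum(V)`.
#'
#' @param ctl,exp [km_curve()] objects for the control and experimental arms
#'   of the same endpoint.
#' @param interval_bounds increasing interval boundaries (months); defaults
#'   to the curves' common native grid.
#' @param followup optional `(lo, hi)` months over which censoring is spread
#'   when no at-risk table is present; defaults to `(0, max time)`.
#' @return a one-row trial-effect data frame (`method = "km_curves"`).
#' @export
loghr_from_km <- function(ctl, exp, interval_bounds = NULL, followup = NULL) {
  if (!inherits(ctl, "km_curve") || !inherits(exp, "km_curve"))
    stop_input("ctl and exp must be km_curve objects")
  if (ctl$endpoint != exp$endpoint)
    stop_input("curves must share an endpoint (got %s vs %s)",
               ctl$endpoint, exp$endpoint)
  if (is.null(interval_bounds))
    interval_bounds <- sort(unique(c(ctl$times, exp$times)))
  tmax <- min(max(ctl$times), max(exp$times))
  interval_bounds <- interval_bounds[interval_bounds <= tmax + 1e-9]
  if (length(interval_bounds) < 2L)
    stop_input("interval_bounds must contain at least two points in the common support")
  s_ctl <- stats::approx(ctl$times, ctl$survival, xout = interval_bounds,
                         method = "constant", rule = 2)$y
  s_exp <- stats::approx(exp$times, exp$survival, xout = interval_bounds,
                         method = "constant", rule = 2)$y
  r_ctl <- effective_at_risk(ctl, utils::head(interval_bounds, -1), followup)
  r_exp <- effective_at_risk(exp, utils::head(interval_bounds, -1), followup)

  sum_ome <- 0; sum_v <- 0; dropped <- 0L
  for (j in seq_len(length(interval_bounds) - 1L)) {
    R1 <- r_ctl[j]; R2 <- r_exp[j]
    if (R1 <= 0 && R2 <= 0) { dropped <- dropped + 1L; next }
    d1 <- if (s_ctl[j] > 0) R1 * (s_ctl[j] - s_ctl[j + 1]) / s_ctl[j] else 0
    d2 <- if (s_exp[j] > 0) R2 * (s_exp[j] - s_exp[j + 1]) / s_exp[j] else 0
    d <- d1 + d2
    N <- R1 + R2
    if (d <= 0 || N <= 1) next  # zero-event intervals contribute nothing
    e2 <- d * R2 / N
    v <- d * (R1 * R2 / N^2) * (N - d) / (N - 1)
    if (v <= 0) next
    sum_ome <- sum_ome + (d2 - e2)
    sum_v <- sum_v + v
  }
  if (dropped > 0L)
    warning(sprintf("trial %s: dropped %d interval(s) with no patients at risk",
                    ctl$trial_id, dropped))
  if (sum_v <= 0)
    stop_input("trial %s: no usable intervals to reconstruct the hazard ratio",
               ctl$trial_id)
  trial_effect(ctl$trial_id, ctl$endpoint, sum_ome / sum_v, 1 / sum_v,
               ctl$n_enrolled + exp$n_enrolled, "km_curves")
}

#' Reconstruct trial effects from a summary table
#'
#' Dispatches each row of a trial-summary table to the direct-CI route when
#' `hr, ci_lo, ci_hi` are present, otherwise to the p-value route; rows with
#' neither are rejected (curve-based trials go through [loghr_from_km()]).
#'
#' @param summaries data frame with columns `trial_id, endpoint, n_exp,
#'   n_ctl, hr, ci_lo, ci_hi, p_value, events_total, direction` (unused
#'   fields `NA`/empty).
#' @return a trial-effect data frame, one row per input row.
#' @export
extract_effects <- function(summaries) {
  need <- c("trial_id", "endpoint", "n_exp", "n_ctl")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop_input("summary table is missing column(s): %s", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    n_tot <- s$n_exp + s$n_ctl
    if (!is.null(s$hr) && is.finite(s$hr) && is.finite(s$ci_lo) && is.finite(s$ci_hi)) {
      loghr_from_hr_ci(s$hr, s$ci_lo, s$ci_hi, n_tot, s$trial_id, s$endpoint)
    } else if (!is.null(s$p_value) && is.finite(s$p_value) &&
               is.finite(s$events_total)) {
      loghr_from_pvalue(s$p_value, s$events_total, s$n_exp, s$n_ctl,
                        s$direction, s$trial_id, s$endpoint)
    } else {
      stop_input("trial %s (%s): neither HR+CI nor p-value+events available",
                 s$trial_id, s$endpoint)
    }
  })
  do.call(rbind, rows)
}

#' Write / read a trial-effect table as CSV
#'
#' Columns: `trial_id, endpoint, loghr, var_loghr, n_total, method`.
#'
#' @param effects trial-effect data frame.
#' @param path file path.
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(effects[, c("trial_id", "endpoint", "loghr", "var_loghr",
                               "n_total", "method")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  eff <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "endpoint", "loghr", "var_loghr", "n_total")
  miss <- setdiff(need, names(eff))
  if (length(miss))
    stop_input("effects CSV is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(eff$var_loghr)) || any(eff$var_loghr <= 0))
    stop_input("effects CSV: var_loghr must be finite and > 0")
  eff
}

#' Write / read Kaplan-Meier curves as long-format CSV
#'
#' Columns: `trial_id, arm, endpoint, time, survival, n_at_risk`
#' (`n_at_risk` may be empty when no at-risk table exists).
#'
#' @param curves a list of [km_curve()] objects.
#' @param path file path.
#' @export
write_km <- function(curves, path) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv)
    data.frame(trial_id = cv$trial_id, arm = cv$arm, endpoint = cv$endpoint,
               time = cv$times, survival = cv$survival,
               n_at_risk = if (is.null(cv$n_at_risk)) NA_real_ else cv$n_at_risk,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_km
#' @param n_enrolled named vector of enrolled counts keyed by
#'   `"trial_id.arm"`; when missing, the first at-risk count is used.
#' @export
read_km <- function(path, n_enrolled = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "arm", "endpoint", "time", "survival")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("KM CSV is missing column(s): %s", paste(miss, collapse = ", "))
  key <- interaction(df$trial_id, df$arm, df$endpoint, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time), ]
    nar <- if ("n_at_risk" %in% names(g) && all(is.finite(g$n_at_risk)))
      g$n_at_risk else NULL
    nk <- paste(g$trial_id[1], g$arm[1], sep = ".")
    n_enr <- if (!is.null(n_enrolled) && nk %in% names(n_enrolled))
      n_enrolled[[nk]] else if (!is.null(nar)) nar[1] else
        stop_input("n_enrolled unknown for %s and no at-risk table", nk)
    km_curve(g$trial_id[1], g$arm[1], g$endpoint[1], g$time, g$survival,
             nar, n_enr)
  })
}
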