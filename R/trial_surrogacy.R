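# match DFS and OS effect tables on trial_id, preserving a canonical order
match_effects <- function(effects_dfs, effects_os) {
  ids <- sort(intersect(effects_dfs$trial_id, effects_os$trial_id))
  if (length(ids) < nrow(effects_dfs) || length(ids) < nrow(effects_os))
    warning("dropping trials present for only one endpoint")
  d <- effects_dfs[match(ids, effects_dfs$trial_id), ]
  o <- effects_os[match(ids, effects_os$trial_id), ]
  data.frame(trial_id = ids, x = d$loghr, y = o$loghr,
             var_x = d$var_loghr, var_y = o$var_loghr,
             n_total = d$n_total, stringsAsFactors = FALSE)
}

trial_weights <- function(m, scheme) {
  w <- switch(scheme,
              n_total = as.numeric(m$n_total),
              inverse_variance = 1 / (m$var_x + m$var_y),
              equal = rep(1, nrow(m)),
              stop_input("unknown weights_scheme '%s'", scheme))
  w * nrow(m) / sum(w)  # normalized to mean 1
}

#' Trial-level surrogacy regression
#'
#' Weighted least squares of the per-trial treatment effect on the true
#' endpoint (log-HR for overall survival) on the effect on the surrogate
#' (log-HR for disease-free survival), with weights proportional to the
#' number of patients per trial by default. Reports the weighted Pearson
#' correlation R with a Fisher-z 95\% confidence interval and the residual
#' scale used by the prediction intervals.
#'
#' @param effects_dfs,effects_os trial-effect data frames (as produced by
#'   the extraction routes) for the surrogate and the true endpoint; matched
#'   on `trial_id`, at least 3 trials.
#' @param weights_scheme `"n_total"` (default), `"inverse_variance"`, or
#'   `"equal"`.
#' @return a list of class `trial_surrogacy_fit`: `slope`, `intercept`,
#'   `resid_scale` (square root of the weighted residual mean square), `r`,
#'   `r_ci`, `n_trials`, `df`, the coefficient covariance `cov`, the mean
#'   trial size `mean_n` (the unit of prediction weights), `weights_scheme`,
#'   and the matched `data`.
#' @export
fit_trial_regression <- function(effects_dfs, effects_os,
                                 weights_scheme = c("n_total",
                                                    "inverse_variance",
                                                    "equal")) {
  weights_scheme <- match.arg(weights_scheme)
  m <- match_effects(effects_dfs, effects_os)
  J <- nrow(m)
  if (J < 3L) stop_input("trial-level regression needs >= 3 matched trials (got %d)", J)
  if (stats::sd(m$x) < 1e-12)
    stop_input("zero variance in the surrogate effects: regression undefined")
  w <- trial_weights(m, weights_scheme)

  X <- cbind(1, m$x)
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * m$y))
  resid <- m$y - X %*% beta
  sigma2 <- sum(w * resid^2) / (J - 2)
  covb <- sigma2 * solve(XtWX)

  sw <- sum(w)
  xb <- sum(w * m$x) / sw; yb <- sum(w * m$y) / sw
  sxx <- sum(w * (m$x - xb)^2); syy <- sum(w * (m$y - yb)^2)
  r <- sum(w * (m$x - xb) * (m$y - yb)) / sqrt(sxx * syy)
  r_ci <- if (J > 3L) {
    z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
    tanh(z + c(-1, 1) * Z975 / sqrt(J - 3))
  } else c(-1, 1)

  structure(list(slope = beta[2], intercept = beta[1],
                 resid_scale = sqrt(sigma2), sigma2 = sigma2,
                 r = r, r_ci = r_ci, n_trials = J, df = J - 2,
                 cov = covb, mean_n = mean(m$n_total),
                 weights_scheme = weights_scheme, data = cbind(m, w = w)),
            class = "trial_surrogacy_fit")
}

#' @export
print.trial_surrogacy_fit <- function(x, ...) {
  cat(sprintf(
    "Trial-level surrogacy regression (%d trials, weights = %s)\n  log-HR(OS) = %.4f + %.4f * log-HR(DFS), residual scale %.4f\n  R = %.3f (95%% CI %.3f-%.3f) -- %s\n",
    x$n_trials, x$weights_scheme, x$intercept, x$slope, x$resid_scale,
    x$r, x$r_ci[1], x$r_ci[2], grade_correlation(x$r)))
  invisible(x)
}

#' Bootstrap-over-trials confidence interval for the trial-level R
#'
#' Resamples whole trials with replacement and recomputes the weighted
#' correlation; an alternative to the Fisher-z interval when the number of
#' trials is small.
#'
#' @inheritParams fit_trial_regression
#' @param n_bootstrap resamples (>= 200).
#' @param seed integer seed.
#' @return percentile 95\% interval for R.
#' @export
bootstrap_r_ci <- function(effects_dfs, effects_os,
                           weights_scheme = "n_total",
                           n_bootstrap = 1000L, seed = 1L) {
  m <- match_effects(effects_dfs, effects_os)
  J <- nrow(m)
  with_seed(seed, {
    rs <- vapply(seq_len(n_bootstrap), function(b) {
      repeat {
        idx <- sample.int(J, J, replace = TRUE)
        if (stats::sd(m$x[idx]) > 1e-12) break
      }
      mm <- m[idx, ]
      w <- trial_weights(mm, weights_scheme)
      sw <- sum(w)
      xb <- sum(w * mm$x) / sw; yb <- sum(w * mm$y) / sw
      sum(w * (mm$x - xb) * (mm$y - yb)) /
        sqrt(sum(w * (mm$x - xb)^2) * sum(w * (mm$y - yb)^2))
    }, numeric(1))
    stats::quantile(rs, c(0.025, 0.975), names = FALSE)
  })
}

# prediction-interval standard error at a new surrogate effect: residual
# variance for a trial of weight w_new plus estimation error of the line
prediction_se <- function(fit, x_new, w_new = 1) {
  xv <- cbind(1, x_new)
  est_var <- rowSums((xv %*% fit$cov) * xv)
  sqrt(pmax(fit$sigma2 / w_new + est_var, 0))
}

#' Predict the OS effect of a new trial from its DFS effect
#'
#' Applies the trial-level regression to a new surrogate effect and returns
#' the estimation-error-adjusted 95\% prediction interval: the variance
#' combines the residual variance (scaled for the new trial's size) with the
#' estimation error of the slope and intercept at that point, using a t
#' quantile with `n_trials - 2` degrees of freedom.
#'
#' @param fit a [fit_trial_regression()] result.
#' @param loghr_dfs_new new trial's log-HR on the surrogate.
#' @param n_new new trial's total patients; `NULL` means an average-sized
#'   trial (relative weight 1).
#' @return a list: `pred`, `lo`, `hi` (log-HR scale), `se`.
#' @export
predict_os_effect <- function(fit, loghr_dfs_new, n_new = NULL) {
  if (!inherits(fit, "trial_surrogacy_fit")) stop_input("'fit' must be a trial_surrogacy_fit")
  w_new <- if (is.null(n_new)) 1 else n_new / fit$mean_n
  pred <- fit$intercept + fit$slope * loghr_dfs_new
  se <- prediction_se(fit, loghr_dfs_new, w_new)
  tq <- stats::qt(0.975, fit$df)
  list(pred = pred, lo = pred - tq * se, hi = pred + tq * se, se = se)
}

#' Surrogate threshold effect
#'
#' The minimum treatment effect on the surrogate needed to predict a
#' non-zero effect on the true endpoint: on the beneficial side, the largest
#' negative log-HR(DFS) at which the upper 95\% prediction limit for
#' log-HR(OS) still touches 0 (reported as an HR at most 1); on the harmful
#' side, the smallest positive log-HR(DFS) at which the lower limit touches
#' 0 (an HR at least 1). Roots are bracketed and solved to |dx| <= 1e-6;
#' a side with no crossing inside `bracket` is `NA`.
#'
#' @param fit a [fit_trial_regression()] result with positive slope;
#'   a non-concordant (non-positive) slope yields both sides `NA` with a
#'   warning.
#' @param n_new trial size at which the prediction variance is evaluated
#'   (`NULL` = average-sized trial).
#' @param bracket search interval on the log-HR(DFS) axis.
#' @return a list: `ste_beneficial`, `ste_harmful` (HR scale), and the
#'   corresponding log-HR roots `x_beneficial`, `x_harmful`.
#' @export
compute_ste <- function(fit, n_new = NULL, bracket = c(-5, 5)) {
  if (!inherits(fit, "trial_surrogacy_fit")) stop_input("'fit' must be a trial_surrogacy_fit")
  if (!all(is.finite(c(fit$slope, fit$intercept, fit$sigma2))))
    stop_input("non-finite regression fit")
  out <- list(ste_beneficial = NA_real_, ste_harmful = NA_real_,
              x_beneficial = NA_real_, x_harmful = NA_real_)
  if (fit$slope <= 0) {
    warning("slope is not positive: surrogate and true effects are not concordant; STE undefined")
    return(out)
  }
  w_new <- if (is.null(n_new)) 1 else n_new / fit$mean_n
  tq <- stats::qt(0.975, fit$df)
  upper <- function(x) fit$intercept + fit$slope * x + tq * prediction_se(fit, x, w_new)
  lower <- function(x) fit$intercept + fit$slope * x - tq * prediction_se(fit, x, w_new)

  # beneficial side: upper limit is convex in x; the crossing nearest 0
  if (upper(0) <= 0) {
    out$x_beneficial <- 0
  } else {
    xmin <- stats::optimize(upper, c(bracket[1], 0))$minimum
    if (upper(xmin) <= 0)
      out$x_beneficial <- stats::uniroot(upper, c(xmin, 0), tol = 1e-9)$root
  }
  # harmful side: lower limit is concave; the crossing nearest 0
  if (lower(0) >= 0) {
    out$x_harmful <- 0
  } else {
    xmax <- stats::optimize(lower, c(0, bracket[2]), maximum = TRUE)$maximum
    if (lower(xmax) >= 0)
      out$x_harmful <- stats::uniroot(lower, c(0, xmax), tol = 1e-9)$root
  }
  out$ste_beneficial <- exp(out$x_beneficial)
  out$ste_harmful <- exp(out$x_harmful)
  out
}

#' Grade a correlation coefficient
#'
#' The conventional surrogacy grading of |value|: above 0.9 excellent, above
#' 0.75 very good, above 0.5 good, above 0.25 moderate, and at or below 0.25
#' poor.
#'
#' @param value correlation in \[-1, 1\].
#' @return one of `"excellent"`, `"very good"`, `"good"`, `"moderate"`,
#'   `"poor"`.
#' @examples
#' grade_correlation(0.988)  # "excellent"
#' grade_correlation(0.815)  # "very good"
#' @export
grade_correlation <- function(value) {
  check_scalar_num(value, "value", lo = -1, hi = 1)
  v <- abs(value)
  if (v > 0.9) "excellent"
  else if (v > 0.75) "very good"
  else if (v > 0.5) "good"
  else if (v > 0.25) "moderate"
  else "poor"
}
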