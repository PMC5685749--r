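#' Trial-level regression scatter plot
#'
#' Per-trial treatment effects (log-HR on the surrogate vs the true
#' endpoint), point area proportional to the number of patients, the fitted
#' weighted regression line, and the 95\% prediction band.
#'
#' @param fit a [fit_trial_regression()] result.
#' @return a ggplot object.
#' @export
plot_trial_regression <- function(fit) {
  d <- fit$data
  xs <- seq(min(d$x) - 0.2, max(d$x) + 0.2, length.out = 100)
  band <- do.call(rbind, lapply(xs, function(x) {
    p <- predict_os_effect(fit, x)
    data.frame(x = x, pred = p$pred, lo = p$lo, hi = p$hi)
  }))
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = x, ymin = lo, ymax = hi),
                         fill = "grey85") +
    ggplot2::geom_line(data = band, ggplot2::aes(x = x, y = pred)) +
    ggplot2::geom_point(data = d,
                        ggplot2::aes(x = x, y = y, size = n_total),
                        shape = 21, fill = "steelblue", alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 10, name = "patients") +
    ggplot2::labs(x = "log HR, disease-free survival",
                  y = "log HR, overall survival",
                  title = sprintf("Trial-level surrogacy: R = %.3f (%s)",
                                  fit$r, grade_correlation(fit$r))) +
    ggplot2::theme_minimal()
}

#' Forest-style leave-one-out cross-validation plot
#'
#' Predicted OS effect with its 95\% prediction interval against the
#' observed effect for each held-out trial; trials whose observed effect
#' falls outside the interval are highlighted.
#'
#' @param cv a [loocv()] result.
#' @return a ggplot object.
#' @export
plot_loocv <- function(cv) {
  d <- cv$records
  d$trial_id <- factor(d$trial_id, levels = rev(d$trial_id))
  ggplot2::ggplot(d, ggplot2::aes(y = trial_id)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = pi_lo, xmax = pi_hi),
                            height = 0.25, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = loghr_os_predicted),
                        shape = 21, fill = "steelblue", size = 2.5) +
    ggplot2::geom_point(ggplot2::aes(x = loghr_os_observed,
                                     colour = inside),
                        shape = 15, size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red"),
                                 name = "inside 95% PI") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "log HR, overall survival", y = NULL,
                  title = sprintf("Leave-one-out validation: %d / %d inside",
                                  cv$summary$n_inside, cv$summary$n_trials)) +
    ggplot2::theme_minimal()
}
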