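# internal helpers shared across modules

Z975 <- 1.959964  # 97.5% normal quantile used in CI inversion throughout

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded package
#' functions do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-trial substream seed; kept below 2^31 - 1
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647L + 48271 * as.numeric(index)) %% 2147483647)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("'%s' must be a finite numeric scalar", name)
  if (strict_lo && x <= lo) stop_input("'%s' must be > %g (got %g)", name, lo, x)
  if (!strict_lo && x < lo) stop_input("'%s' must be >= %g (got %g)", name, lo, x)
  if (x > hi) stop_input("'%s' must be <= %g (got %g)", name, hi, x)
  invisible(x)
}

# step-function evaluation of a Kaplan-Meier fit at arbitrary times
km_step_at <- function(time, event, at) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  sf(at)
}
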