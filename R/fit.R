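#' Single-exponential dwell-time fit with bootstrap confidence interval
#'
#' Fits an exponential distribution to a sample of durations (segment
#' dwell times, pause durations, trace durations) by maximum likelihood
#' — for an uncensored exponential the MLE of the mean is the sample
#' mean — and attaches a 95% confidence interval from a nonparametric
#' bootstrap: the 2.5 and 97.5 percentiles of `n_boot` resample means.
#' Censoring is not modelled. Resampling uses R's global random number
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param durations Numeric vector of durations (s); at least 2 finite
#'   positive values (10 or more recommended for a meaningful fit).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @return An `exp_fit` object: list with `mean_duration`, `rate`
#'   (`1/mean_duration`), `ci95_low`, `ci95_high`, `n_boot`, `n_obs`.
#' @examples
#' set.seed(1)
#' fit_exponential(rexp(200, rate = 1 / 5))
#' @export
fit_exponential <- function(durations, n_boot = 1000) {
  durations <- durations[is.finite(durations)]
  if (length(durations) < 2L) stop("need at least 2 finite durations")
  if (any(durations < 0)) stop("durations must be non-negative")
  if (length(durations) < 10L) {
    warning("fewer than 10 observations; fit will be unstable")
  }
  m <- mean(durations)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(durations, replace = TRUE))
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  structure(list(mean_duration = m, rate = 1 / m,
                 ci95_low = min(ci[1], m), ci95_high = max(ci[2], m),
                 n_boot = n_boot, n_obs = length(durations)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> mean duration %.3g s (95%% CI %.3g-%.3g, %d bootstrap, n = %d)\n",
    x$mean_duration, x$ci95_low, x$ci95_high, x$n_boot, x$n_obs))
  invisible(x)
}
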