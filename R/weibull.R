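# Weibull failure-type classification of onset samples.
#
# The hazard of a two-parameter Weibull is decreasing, constant or increasing
# as the shape is <1, =1 or >1. In pharmacovigilance the convention reads the
# bootstrap CI of the shape against 1: early failure when the whole CI is
# below 1, wear-out when it is above 1, random failure when it straddles 1.

#' Fit a Weibull distribution to an onset sample
#'
#' Two-parameter Weibull by maximum likelihood (no censoring: only reports
#' with observed onsets enter). The shape CI is a nonparametric bootstrap
#' percentile interval over `ci_reps` resamples; the failure type follows
#' from that CI against 1 (`early` if the CI is entirely below 1, `wear_out`
#' entirely above, `random` when it contains 1).
#'
#' @param days Positive numeric vector of onset intervals (NAs dropped),
#'   at least 10 observations.
#' @param ci_reps Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed for the bootstrap resampling.
#' @param conf Confidence level of the percentile interval (default 0.95).
#' @return A `weibull_fit`: list with `shape`, `scale`, `shape_ci_low`,
#'   `shape_ci_high`, `n`, `failure_type`, `ci_reps`.
#' @examples
#' set.seed(1)
#' fit_weibull(rweibull(500, shape = 0.7, scale = 100), ci_reps = 200, seed = 2)
#' @export
fit_weibull <- function(days, ci_reps = 1000L, seed = NULL, conf = 0.95) {
  days <- days[!is.na(days)]
  if (length(days) < 10L) {
    stop("Weibull fit needs at least 10 onset observations (got ",
         length(days), ")", call. = FALSE)
  }
  if (any(days <= 0)) {
    stop("onset intervals must be positive", call. = FALSE)
  }
  fit <- weibull_mle_cpp(as.numeric(days))
  if (!fit$converged) {
    stop("Weibull maximum likelihood did not converge (degenerate sample)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  boot <- weibull_shape_boot_cpp(as.numeric(days), as.integer(ci_reps))
  boot <- boot[!is.na(boot)]
  if (length(boot) < ci_reps * 0.5) {
    stop("bootstrap failed to refit on most resamples", call. = FALSE)
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  failure_type <- if (ci[2] < 1) "early"
    else if (ci[1] > 1) "wear_out"
    else "random"
  structure(list(shape = fit$shape, scale = fit$scale,
                 shape_ci_low = ci[1], shape_ci_high = ci[2],
                 n = length(days), failure_type = failure_type,
                 ci_reps = length(boot)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n=%d shape=%.3f (%.3f-%.3f) scale=%.1f days -> %s failure\n",
    x$n, x$shape, x$shape_ci_low, x$shape_ci_high, x$scale, x$failure_type))
  invisible(x)
}

#' Weibull log-likelihood
#'
#' @param days Positive numeric vector.
#' @param shape,scale Weibull parameters.
#' @return Scalar log-likelihood.
#' @export
weibull_loglik <- function(days, shape, scale) {
  sum(stats::dweibull(days, shape = shape, scale = scale, log = TRUE))
}
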