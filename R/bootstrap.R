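# Bias-corrected and accelerated (BCa) bootstrap over MA lines. The
# resampling unit is the line: resampling lines resamples their
# (m, n, T) triples jointly, so variation in callable sites and
# generations across lines is carried into the interval.

#' BCa bootstrap confidence interval for a statistic of MA lines
#'
#' Resamples the rows of `lines` with replacement `B` times and forms the
#' bias-corrected and accelerated interval: the bias correction `z0` is
#' the normal quantile of the fraction of bootstrap replicates below the
#' point estimate, and the acceleration `a` comes from the jackknife
#' skewness formula
#' `a = sum((mean(jk) - jk)^3) / (6 * sum((mean(jk) - jk)^2)^(3/2))`.
#' If every bootstrap replicate is identical the interval degenerates and
#' the percentile interval (here: the point itself) is returned with a
#' warning.
#'
#' @param lines A tibble of MA lines (any columns the statistic needs), or
#'   a plain numeric vector.
#' @param statistic Function of a resampled `lines` object returning one
#'   number (default: the mean of a numeric vector).
#' @param B Number of bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling.
#' @return A list: `point`, `ci_low`, `ci_high`, `z0`, `accel`, `B`,
#'   `method` (`"bca_bootstrap"` or `"percentile_degenerate"`).
#' @export
#' @examples
#' bca_bootstrap_ci(c(1.2, 0.8, 1.1, 0.9, 1.4, 0.7), B = 500, seed = 1)
bca_bootstrap_ci <- function(lines, statistic = mean, B = 1000L,
                             conf = 0.95, seed = NULL) {
  run <- function() .bca_impl(lines, statistic, B, conf)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.resample <- function(lines, idx) {
  if (is.data.frame(lines)) lines[idx, , drop = FALSE] else lines[idx]
}

.bca_impl <- function(lines, statistic, B, conf) {
  n <- if (is.data.frame(lines)) nrow(lines) else length(lines)
  if (n < 3) abort("BCa bootstrap needs at least 3 lines")
  theta_hat <- statistic(lines)

  boots <- vapply(seq_len(B), function(b) {
    statistic(.resample(lines, sample.int(n, n, replace = TRUE)))
  }, numeric(1))

  alpha <- (1 - conf) / 2
  if (length(unique(boots)) == 1L) {
    warn("degenerate bootstrap distribution; falling back to percentile interval")
    return(list(point = theta_hat, ci_low = boots[1], ci_high = boots[1],
                z0 = 0, accel = 0, B = B, method = "percentile_degenerate"))
  }

  prop_below <- mean(boots < theta_hat)
  # guard the probit at the boundaries (all replicates on one side)
  prop_below <- min(max(prop_below, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(prop_below)

  jack <- vapply(seq_len(n), function(i) {
    statistic(.resample(lines, setdiff(seq_len(n), i)))
  }, numeric(1))
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)

  zlo <- qnorm(alpha); zhi <- qnorm(1 - alpha)
  a1 <- pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  a2 <- pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  ci <- unname(quantile(boots, probs = c(a1, a2), type = 6, names = FALSE))
  list(point = theta_hat, ci_low = ci[1], ci_high = ci[2],
       z0 = z0, accel = a, B = B, method = "bca_bootstrap")
}
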