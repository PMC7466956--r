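# broom-style tidy()/glance() methods for the fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @rdname tidy_mutacc
#' @param x A `"rate_estimate"`, `"indel_rates"`, `"poisson_gof"`,
#'   `"mnm_result"`, `"ne_estimate"` or `"ma_analysis"` object.
#' @param ... Unused.
tidy.rate_estimate <- function(x, ...) {
  tibble(
    term = x$rate_col, estimate = x$point, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high, method = x$method
  )
}

#' @export
#' @rdname tidy_mutacc
#' @method glance rate_estimate
glance.rate_estimate <- function(x, ...) {
  tibble(n_lines = x$n_lines, pooled = x$pooled, B = x$B, conf = x$conf)
}

#' @export
#' @rdname tidy_mutacc
#' @method tidy indel_rates
tidy.indel_rates <- function(x, ...) {
  bind_rows(tidy(x$total), tidy(x$insertion), tidy(x$deletion))
}

#' @export
#' @rdname tidy_mutacc
#' @method tidy poisson_gof
tidy.poisson_gof <- function(x, ...) x$bins

#' @export
#' @rdname tidy_mutacc
#' @method glance poisson_gof
glance.poisson_gof <- function(x, ...) {
  tibble(lambda = x$lambda, statistic = x$chi_square, df = x$df,
         p.value = x$p_value)
}

#' @export
#' @rdname tidy_mutacc
#' @method tidy mnm_result
tidy.mnm_result <- function(x, ...) x$clusters

#' @export
#' @rdname tidy_mutacc
#' @method glance mnm_result
glance.mnm_result <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_clustered_mutations = sum(x$clusters$size),
    n_events = sum(x$events$n_events),
    n_raw = sum(x$events$n_raw)
  )
}

#' @export
#' @rdname tidy_mutacc
#' @method tidy ne_estimate
tidy.ne_estimate <- function(x, ...) {
  tibble(term = "Ne", estimate = x$ne, conf.low = x$ci_low,
         conf.high = x$ci_high, theta = x$theta, mu = x$mu)
}

#' Tidy and glance methods for mutacc result objects
#'
#' @name tidy_mutacc
#' @return A tibble summarising the object: one row per term/cluster/bin
#'   for `tidy()`, one row of model-level statistics for `glance()`.
NULL

#' @export
#' @rdname tidy_mutacc
#' @method tidy ma_analysis
tidy.ma_analysis <- function(x, ...) {
  bind_rows(
    tidy(x$rate_bs),
    mutate(tidy(x$rate_bs_corrected), term = "rate_bs_corrected"),
    tidy(x$indel)
  )
}

#' @export
#' @rdname tidy_mutacc
#' @method glance ma_analysis
glance.ma_analysis <- function(x, ...) {
  tibble(
    n_lines = nrow(x$lines),
    n_substitutions = x$effects$n_substitutions,
    n_indels = x$effects$n_indels,
    ts_tv = x$ts_tv,
    equilibrium_gc = x$equilibrium_gc,
    gc_bias = x$bias$gc_bias,
    mnm_clusters = nrow(x$mnm$clusters),
    poisson_raw_p = x$poisson_raw$p_value,
    poisson_corrected_p = x$poisson_corrected$p_value,
    ne = if (is.null(x$ne)) NA_real_ else x$ne$ne
  )
}
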