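# Mutation-rate estimation. The per-line estimator is mu = m / (n * T)
# (m observed mutations, n callable sites, T generations); the experiment
# rate is the unweighted mean of per-line rates with SE = sd / sqrt(n_lines)
# and a BCa bootstrap interval over lines. The six-class strand-symmetric
# spectrum feeds conditional A/T <-> G/C rates, the mutation-equilibrium GC
# content, the GC-direction bias ratio, and Ts/Tv.

#' Per-line mutation rate
#'
#' @param m Observed mutation count(s).
#' @param n Callable sites analysed in the line(s).
#' @param T_gen Generations elapsed in the line(s).
#' @return `m / (n * T_gen)`, per site per generation (vectorised).
#' @export
#' @examples
#' per_line_rate(2, 1e6, 100)   # 2e-8
per_line_rate <- function(m, n, T_gen) {
  if (any(n <= 0) || any(T_gen <= 0)) abort("n and T_gen must be > 0")
  if (any(m < 0)) abort("m must be >= 0")
  m / (n * T_gen)
}

#' Per-line mutation counts and rates
#'
#' Counts substitutions and indels per line and computes per-line rates.
#' Pass MNM-corrected substitution counts via `bs_counts` to rate
#' clustered events as single mutations.
#'
#' @param lines Lines tibble (`line_id`, `generations`, `callable_sites`,
#'   optionally `callable_AT_sites`, `callable_GC_sites`, `lab`).
#' @param mutations Mutation tibble.
#' @param bs_counts Optional tibble `line_id`, `m_bs` overriding the raw
#'   substitution count (e.g. MNM-collapsed event counts).
#' @return Tibble with one row per line: counts `m_bs`, `m_ins`, `m_del`,
#'   `m_indel` and rates `rate_bs`, `rate_ins`, `rate_del`, `rate_indel`.
#' @export
per_line_rates <- function(lines, mutations, bs_counts = NULL) {
  .assert_lines(lines)
  .assert_mutations(mutations)
  counts <- mutations %>%
    group_by(.data$line_id) %>%
    summarise(
      m_bs = sum(.data$mclass == "substitution"),
      m_ins = sum(.data$mclass == "insertion"),
      m_del = sum(.data$mclass == "deletion"),
      .groups = "drop"
    )
  out <- lines %>%
    left_join(counts, by = "line_id") %>%
    mutate(dplyr::across(dplyr::all_of(c("m_bs", "m_ins", "m_del")),
                         ~dplyr::coalesce(.x, 0L)))
  if (!is.null(bs_counts)) {
    out <- out %>%
      left_join(rename(bs_counts, m_bs_override = "m_bs"), by = "line_id") %>%
      mutate(m_bs = dplyr::coalesce(.data$m_bs_override, .data$m_bs)) %>%
      select(-"m_bs_override")
  }
  out %>%
    mutate(
      m_indel = .data$m_ins + .data$m_del,
      rate_bs = per_line_rate(.data$m_bs, .data$callable_sites, .data$generations),
      rate_ins = per_line_rate(.data$m_ins, .data$callable_sites, .data$generations),
      rate_del = per_line_rate(.data$m_del, .data$callable_sites, .data$generations),
      rate_indel = per_line_rate(.data$m_indel, .data$callable_sites, .data$generations)
    )
}

#' Experiment-wide mutation rate with bootstrap CI
#'
#' The point estimate is the unweighted mean of per-line rates (matching
#' the per-line-then-average design of MA studies) and the SE is the
#' standard deviation of per-line rates over `sqrt(n_lines)`. A pooled
#' alternative, `sum(m) / sum(n * T)`, is reported alongside. With >= 3
#' lines a BCa bootstrap interval over lines is attached.
#'
#' @param rates_df Output of [per_line_rates()] (or any tibble with the
#'   rate column and `callable_sites`, `generations`).
#' @param rate_col Which per-line rate column to summarise
#'   (default `"rate_bs"`).
#' @param B Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return A `"rate_estimate"`: `point`, `se`, `ci_low`, `ci_high`,
#'   `n_lines`, `pooled`, `method`, `B`.
#' @export
experiment_rate <- function(rates_df, rate_col = "rate_bs", B = 1000L,
                            conf = 0.95, seed = NULL) {
  r <- rates_df[[rate_col]]
  if (is.null(r)) abort(paste0("no column ", rate_col, " in rates_df"))
  n_lines <- length(r)
  point <- mean(r)
  se <- if (n_lines >= 2) sd(r) / sqrt(n_lines) else NA_real_
  count_col <- sub("^rate", "m", rate_col)
  pooled <- if (count_col %in% names(rates_df)) {
    sum(rates_df[[count_col]]) /
      sum(rates_df$callable_sites * rates_df$generations)
  } else {
    NA_real_
  }
  ci <- if (n_lines >= 3) {
    bca_bootstrap_ci(r, statistic = mean, B = B, conf = conf, seed = seed)
  } else {
    list(ci_low = NA_real_, ci_high = NA_real_, method = "per_line_mean")
  }
  structure(
    list(point = point, se = se, ci_low = ci$ci_low, ci_high = ci$ci_high,
         n_lines = n_lines, pooled = pooled, conf = conf,
         method = ci$method, B = B, rate_col = rate_col),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %s: %.3g (SE %.2g) per site per generation\n",
    x$rate_col, x$point, x$se
  ))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  %.0f%% %s CI: [%.3g, %.3g], %d lines\n",
                100 * x$conf, x$method, x$ci_low, x$ci_high, x$n_lines))
  }
  invisible(x)
}

#' Six-class substitution spectrum counts
#'
#' Classes are strand-symmetric (an A->G on the reference strand and a
#' T->C both count as A:T -> G:C transitions).
#'
#' @param mutations A mutation tibble (only substitutions are counted).
#' @return A `"spectrum_counts"` tibble: `class`, `count`, `type`
#'   (`ts`/`tv`), with one row per class in canonical order.
#' @export
spectrum_counts <- function(mutations) {
  .assert_mutations(mutations)
  subs <- filter(mutations, .data$mclass == "substitution")
  cls <- if (nrow(subs) > 0) substitution_class(subs$ref, subs$alt) else character(0)
  tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
  out <- tibble(
    class = SPECTRUM_CLASSES,
    count = as.integer(tab),
    type = if_else(stringr::str_ends(SPECTRUM_CLASSES, "_ts"), "ts", "tv")
  )
  structure(out, class = c("spectrum_counts", class(out)))
}

#' Transition/transversion ratio
#'
#' @param spectrum A [spectrum_counts()] tibble.
#' @return `transitions / transversions`. Zero transversions give `Inf`
#'   with a warning.
#' @export
#' @examples
#' # 11 transitions vs 26 transversions -> 0.423
ts_tv_ratio <- function(spectrum) {
  ts <- sum(spectrum$count[spectrum$type == "ts"])
  tv <- sum(spectrum$count[spectrum$type == "tv"])
  if (tv == 0) {
    warn("no transversions observed; Ts/Tv is infinite")
    return(Inf)
  }
  ts / tv
}

#' Conditional A/T -> G/C and G/C -> A/T mutation rates
#'
#' The GC-changing classes are divided by the summed site-generations of
#' the matching base pair: `mu_ATtoGC = (AT>GC ts + AT>CG tv) /
#' sum(n_AT_i * T_i)` and `mu_GCtoAT = (GC>AT ts + GC>TA tv) /
#' sum(n_GC_i * T_i)`. The GC-conservative classes (A:T -> T:A and
#' G:C -> C:G) contribute to neither. Denominators pool site-generations
#' across lines by default; `per_line = TRUE` instead averages per-line
#' conditional rates.
#'
#' @param spectrum A [spectrum_counts()] tibble (pooled mode), or the
#'   mutation tibble itself when `per_line = TRUE`.
#' @param lines Lines tibble with `callable_AT_sites`,
#'   `callable_GC_sites`, `generations`.
#' @param per_line Average per-line conditional rates instead of pooling
#'   denominators.
#' @return Tibble: `mu_ATtoGC`, `mu_GCtoAT`, plus the class counts and
#'   denominators used.
#' @export
conditional_rates <- function(spectrum, lines, per_line = FALSE) {
  .assert_lines(lines, need = c("line_id", "generations",
                                "callable_AT_sites", "callable_GC_sites"))
  denom_AT <- sum(lines$callable_AT_sites * lines$generations)
  denom_GC <- sum(lines$callable_GC_sites * lines$generations)
  if (denom_AT <= 0 || denom_GC <= 0) abort("zero site-generation denominator")

  if (per_line) {
    muts <- spectrum
    .assert_mutations(muts)
    per <- lines %>%
      left_join(
        muts %>%
          filter(.data$mclass == "substitution") %>%
          mutate(class = substitution_class(.data$ref, .data$alt)) %>%
          group_by(.data$line_id) %>%
          summarise(
            m_at = sum(.data$class %in% c("AT_to_GC_ts", "AT_to_CG_tv")),
            m_gc = sum(.data$class %in% c("GC_to_AT_ts", "GC_to_TA_tv")),
            .groups = "drop"
          ),
        by = "line_id"
      ) %>%
      mutate(
        m_at = dplyr::coalesce(.data$m_at, 0L),
        m_gc = dplyr::coalesce(.data$m_gc, 0L)
      )
    return(tibble(
      mu_ATtoGC = mean(per$m_at / (per$callable_AT_sites * per$generations)),
      mu_GCtoAT = mean(per$m_gc / (per$callable_GC_sites * per$generations)),
      m_ATtoGC = sum(per$m_at), m_GCtoAT = sum(per$m_gc),
      denom_AT = denom_AT, denom_GC = denom_GC, method = "per_line_mean"
    ))
  }

  cnt <- setNames(spectrum$count, spectrum$class)
  m_at <- sum(cnt[c("AT_to_GC_ts", "AT_to_CG_tv")])
  m_gc <- sum(cnt[c("GC_to_AT_ts", "GC_to_TA_tv")])
  tibble(
    mu_ATtoGC = m_at / denom_AT, mu_GCtoAT = m_gc / denom_GC,
    m_ATtoGC = m_at, m_GCtoAT = m_gc,
    denom_AT = denom_AT, denom_GC = denom_GC, method = "pooled"
  )
}

#' GC content at mutation equilibrium
#'
#' The GC fraction a neutrally evolving sequence approaches under the
#' conditional rates alone: `mu_ATtoGC / (mu_GCtoAT + mu_ATtoGC)`.
#'
#' @param mu_ATtoGC,mu_GCtoAT Conditional rates (per site per generation).
#' @return Equilibrium GC fraction in `[0, 1]`.
#' @export
#' @examples
#' equilibrium_gc(0.44e-11, 4.36e-11)   # ~0.092
equilibrium_gc <- function(mu_ATtoGC, mu_GCtoAT) {
  if (mu_ATtoGC < 0 || mu_GCtoAT < 0) abort("rates must be >= 0")
  if (mu_ATtoGC + mu_GCtoAT == 0) abort("both conditional rates are zero")
  mu_ATtoGC / (mu_GCtoAT + mu_ATtoGC)
}

#' Mutation bias ratio in the G/C direction
#'
#' @param mu_ATtoGC,mu_GCtoAT Conditional rates.
#' @return Tibble: `gc_bias = mu_ATtoGC / mu_GCtoAT` and its reciprocal
#'   `at_bias` (the fold bias toward A/T).
#' @export
bias_ratio <- function(mu_ATtoGC, mu_GCtoAT) {
  if (mu_GCtoAT <= 0) abort("mu_GCtoAT must be > 0")
  tibble(gc_bias = mu_ATtoGC / mu_GCtoAT, at_bias = mu_GCtoAT / mu_ATtoGC)
}

#' Indel mutation rates with a lab comparison
#'
#' Per-line `m / (n T)` restricted to indels (total, insertions,
#' deletions), summarised like [experiment_rate()], plus a Welch
#' two-sample t-test on per-line total indel rates between the two labs
#' (when a `lab` column with exactly two levels is present).
#'
#' @inheritParams experiment_rate
#' @param lines Lines tibble.
#' @param mutations Mutation tibble.
#' @return A list of class `"indel_rates"`: `total`, `insertion`,
#'   `deletion` (each a `"rate_estimate"`), `per_line` (the rates tibble)
#'   and `lab_test` (tibble with `t`, `df`, `p_value`, or `NULL`).
#' @export
indel_rates <- function(lines, mutations, B = 1000L, seed = NULL) {
  pl <- per_line_rates(lines, mutations)
  out <- list(
    total = experiment_rate(pl, "rate_indel", B = B, seed = seed),
    insertion = experiment_rate(pl, "rate_ins", B = B, seed = seed),
    deletion = experiment_rate(pl, "rate_del", B = B, seed = seed),
    per_line = pl,
    lab_test = NULL
  )
  if ("lab" %in% names(pl) && dplyr::n_distinct(pl$lab) == 2 &&
      all(table(pl$lab) >= 2)) {
    tt <- t.test(rate_indel ~ lab, data = pl)
    out$lab_test <- tibble(t = unname(tt$statistic),
                           df = unname(tt$parameter),
                           p_value = tt$p.value)
  }
  structure(out, class = "indel_rates")
}

#' @export
print.indel_rates <- function(x, ...) {
  cat("<indel_rates>\n")
  for (k in c("total", "insertion", "deletion")) {
    cat(sprintf("  %-9s %.3g (SE %.2g)\n", k, x[[k]]$point, x[[k]]$se))
  }
  if (!is.null(x$lab_test)) {
    cat(sprintf("  lab Welch t-test: t = %.3g, P = %.3g\n",
                x$lab_test$t, x$lab_test$p_value))
  }
  invisible(x)
}
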