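# Effective population size from nucleotide diversity, and the full
# experiment-level analysis that stitches every stage together into a
# single reproducible report.

#' Effective population size from nucleotide diversity
#'
#' For haploids the expected nucleotide diversity is `theta = 2 * Ne * mu`,
#' so `Ne = theta / (2 * mu)`. When `mu` carries a bootstrap CI the bounds
#' propagate monotonically: `Ne_low = theta / (2 * mu_high)` and
#' `Ne_high = theta / (2 * mu_low)`.
#'
#' @param theta Per-site nucleotide diversity (standing heterozygosity).
#' @param mu A base-substitution rate (number) or a `"rate_estimate"`.
#' @return A `"ne_estimate"`: `theta`, `mu`, `ne`, `ci_low`, `ci_high`,
#'   `ci_method`.
#' @export
#' @examples
#' estimate_ne(0.00076, 2.47e-11)   # ~1.5e7
estimate_ne <- function(theta, mu) {
  if (theta <= 0) abort("theta must be > 0")
  est <- if (inherits(mu, "rate_estimate")) mu else NULL
  mu_point <- if (is.null(est)) mu else est$point
  if (!is.numeric(mu_point) || mu_point <= 0) abort("mu must be > 0")
  ci_low <- ci_high <- NA_real_
  ci_method <- "none"
  if (!is.null(est) && !is.na(est$ci_low) && est$ci_low > 0) {
    ci_low <- theta / (2 * est$ci_high)
    ci_high <- theta / (2 * est$ci_low)
    ci_method <- paste0("monotone transform of mu ", est$method, " CI")
  }
  structure(
    list(theta = theta, mu = mu_point, ne = theta / (2 * mu_point),
         ci_low = ci_low, ci_high = ci_high, ci_method = ci_method),
    class = "ne_estimate"
  )
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate> Ne = %.3g (theta = %.3g, mu = %.3g)\n",
              x$ne, x$theta, x$mu))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% CI: [%.3g, %.3g] (%s)\n", x$ci_low, x$ci_high,
                x$ci_method))
  }
  invisible(x)
}

#' Full MA-experiment analysis
#'
#' Runs the complete downstream pipeline on loaded data: SSR annotation,
#' MNM clustering and collapse, per-line and experiment-wide rates (raw
#' and MNM-corrected) with BCa bootstrap CIs, the six-class spectrum with
#' conditional rates, equilibrium GC and bias ratio, Poisson
#' goodness-of-fit before and after cluster collapse, functional-effect
#' classification and SSR enrichment, indel accounting, and (when `theta`
#' is given) the effective population size.
#'
#' @param lines Lines tibble (`line_id`, `lab`, `generations`,
#'   `callable_sites`, `callable_AT_sites`, `callable_GC_sites`).
#' @param mutations Mutation tibble (all lines).
#' @param reference A [read_reference()] result.
#' @param gene_models Optional [read_gene_models()] tibble; skips effect
#'   classification when `NULL`.
#' @param ssr_loci Optional SSR locus tibble; computed with [find_ssrs()]
#'   defaults when `NULL`.
#' @param masks Optional tibble of per-line callable intervals, used for
#'   the callable SSR fraction; falls back to whole-genome fraction.
#' @param theta Optional nucleotide diversity for the Ne estimate.
#' @param window MNM window in bp (default 50).
#' @param B Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `"ma_analysis"` with components `lines`,
#'   `mutations` (annotated), `per_line`, `rate_bs`, `rate_bs_corrected`,
#'   `indel`, `spectrum`, `ts_tv`, `conditional`, `equilibrium_gc`,
#'   `bias`, `mnm`, `mnm_probability`, `poisson_raw`,
#'   `poisson_corrected`, `effects`, `ssr_fraction`, `ssr_enrichment`,
#'   `indel_acct`, `ne`.
#' @export
analyze_ma <- function(lines, mutations, reference, gene_models = NULL,
                       ssr_loci = NULL, masks = NULL, theta = NULL,
                       window = 50L, B = 1000L, seed = 1L) {
  .assert_lines(lines)
  .assert_mutations(mutations)
  if (is.null(ssr_loci)) ssr_loci <- find_ssrs(reference)
  mutations <- annotate_variants_ssr(mutations, ssr_loci)
  if (!is.null(gene_models)) {
    mutations <- classify_effects(mutations, gene_models, reference)
  }

  mnm <- detect_mnms(mutations, window = window)
  # corrected substitution event counts: cluster members collapse to one
  sub_events <- .corrected_sub_counts(mnm, lines)

  per_line <- per_line_rates(lines, mutations)
  per_line_corr <- per_line_rates(lines, mutations, bs_counts = sub_events)

  rate_bs <- experiment_rate(per_line, "rate_bs", B = B, seed = seed)
  rate_bs_corr <- experiment_rate(per_line_corr, "rate_bs", B = B,
                                  seed = seed + 1L)
  indel <- indel_rates(lines, mutations, B = B, seed = seed + 2L)

  spectrum <- spectrum_counts(mutations)
  tstv <- ts_tv_ratio(spectrum)
  cond <- conditional_rates(spectrum, lines)
  eq_gc <- equilibrium_gc(cond$mu_ATtoGC, cond$mu_GCtoAT)
  bias <- bias_ratio(cond$mu_ATtoGC, cond$mu_GCtoAT)

  raw_counts <- per_line$m_bs + per_line$m_indel
  corr_counts <- lines %>%
    select("line_id") %>%
    left_join(mnm$events, by = "line_id") %>%
    mutate(n_events = dplyr::coalesce(.data$n_events, 0L)) %>%
    pull("n_events")
  poisson_raw <- poisson_gof(raw_counts)
  poisson_corr <- poisson_gof(corr_counts)

  mnm_prob <- expected_mnm_probability_experiment(
    tibble(m = raw_counts, n = lines$callable_sites), window = window
  )

  ssr_frac <- if (!is.null(masks)) {
    ssr_genome_fraction(ssr_loci, masks)
  } else {
    ssr_genome_fraction(
      ssr_loci,
      tibble(chrom = names(reference), start = 0L,
             end = Biostrings::width(reference))
    )
  }

  effects <- effect_summary(mutations)
  enrich_subs <- ssr_enrichment_test(effects$n_subs_in_ssr,
                                     max(effects$n_substitutions, 1L),
                                     ssr_frac)
  enrich_ind <- ssr_enrichment_test(effects$n_indels_in_ssr,
                                    max(effects$n_indels, 1L), ssr_frac)
  acct <- indel_accounting(mutations, lines)
  ne <- if (!is.null(theta)) estimate_ne(theta, rate_bs) else NULL

  structure(
    list(
      lines = lines, mutations = mutations, per_line = per_line,
      per_line_corrected = per_line_corr,
      rate_bs = rate_bs, rate_bs_corrected = rate_bs_corr, indel = indel,
      spectrum = spectrum, ts_tv = tstv, conditional = cond,
      equilibrium_gc = eq_gc, bias = bias,
      mnm = mnm, mnm_probability = mnm_prob,
      poisson_raw = poisson_raw, poisson_corrected = poisson_corr,
      effects = effects, ssr_loci = ssr_loci, ssr_fraction = ssr_frac,
      ssr_enrichment = list(substitutions = enrich_subs, indels = enrich_ind),
      indel_acct = acct, ne = ne,
      params = list(window = window, B = B, seed = seed)
    ),
    class = "ma_analysis"
  )
}

# corrected per-line substitution event counts from an mnm_result
.corrected_sub_counts <- function(mnm, lines) {
  subs <- filter(mnm$members, .data$mclass == "substitution")
  counts <- subs %>%
    group_by(.data$line_id) %>%
    summarise(
      m_bs = sum(is.na(.data$cluster_id)) +
        dplyr::n_distinct(.data$cluster_id, na.rm = TRUE),
      .groups = "drop"
    )
  lines %>%
    select("line_id") %>%
    left_join(counts, by = "line_id") %>%
    mutate(m_bs = dplyr::coalesce(.data$m_bs, 0L))
}

#' @export
print.ma_analysis <- function(x, ...) {
  cat("<ma_analysis>\n")
  cat(sprintf("  lines: %d, substitutions: %d, indels: %d\n",
              nrow(x$lines), x$effects$n_substitutions, x$effects$n_indels))
  cat(sprintf("  mu_bs = %.3g (SE %.2g), mu_indel = %.3g (SE %.2g)\n",
              x$rate_bs$point, x$rate_bs$se,
              x$indel$total$point, x$indel$total$se))
  cat(sprintf("  Ts/Tv = %.3g, equilibrium GC = %.3g, GC-bias = %.3g\n",
              x$ts_tv, x$equilibrium_gc, x$bias$gc_bias))
  if (!is.null(x$ne)) cat(sprintf("  Ne = %.3g\n", x$ne$ne))
  invisible(x)
}

#' Consolidated report of an MA analysis
#'
#' Flattens an [analyze_ma()] result into a named list of statistics,
#' written as deterministic JSON (sorted keys, fixed float handling) and
#' a Table-style TSV of headline counts and rates. Rates are also
#' presented scaled by 1e11 with two decimals, the conventional display
#' for MA studies of this magnitude.
#'
#' @param analysis An `"ma_analysis"`.
#' @param dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return Invisibly, the report list.
#' @export
build_report <- function(analysis, dir = NULL) {
  stopifnot(inherits(analysis, "ma_analysis"))
  a <- analysis
  report <- list(
    n_lines = nrow(a$lines),
    n_substitutions = a$effects$n_substitutions,
    n_indels = a$effects$n_indels,
    mu_bs = a$rate_bs$point, mu_bs_se = a$rate_bs$se,
    mu_bs_ci_low = a$rate_bs$ci_low, mu_bs_ci_high = a$rate_bs$ci_high,
    mu_bs_x1e11 = round(a$rate_bs$point * 1e11, 2),
    mu_bs_corrected = a$rate_bs_corrected$point,
    mu_indel = a$indel$total$point, mu_indel_se = a$indel$total$se,
    mu_indel_ci_low = a$indel$total$ci_low,
    mu_indel_ci_high = a$indel$total$ci_high,
    mu_indel_x1e11 = round(a$indel$total$point * 1e11, 2),
    mu_insertion = a$indel$insertion$point,
    mu_deletion = a$indel$deletion$point,
    ts_tv = a$ts_tv,
    mu_ATtoGC = a$conditional$mu_ATtoGC,
    mu_GCtoAT = a$conditional$mu_GCtoAT,
    equilibrium_gc_percent = 100 * a$equilibrium_gc,
    gc_bias = a$bias$gc_bias, at_bias = a$bias$at_bias,
    mnm_clusters = nrow(a$mnm$clusters),
    mnm_probability = a$mnm_probability,
    poisson_raw_chi2 = a$poisson_raw$chi_square,
    poisson_raw_p = a$poisson_raw$p_value,
    poisson_corrected_chi2 = a$poisson_corrected$chi_square,
    poisson_corrected_p = a$poisson_corrected$p_value,
    n_synonymous = a$effects$n_synonymous,
    n_nonsynonymous = a$effects$n_nonsynonymous,
    n_noncoding_subs = a$effects$n_noncoding_subs,
    n_subs_in_ssr = a$effects$n_subs_in_ssr,
    n_indels_in_ssr = a$effects$n_indels_in_ssr,
    ssr_fraction = a$ssr_fraction,
    ssr_enrichment_p_subs = a$ssr_enrichment$substitutions$p_value,
    ssr_enrichment_p_indels = a$ssr_enrichment$indels$p_value,
    inserted_bp = a$indel_acct$inserted_bp,
    deleted_bp = a$indel_acct$deleted_bp,
    net_bp = a$indel_acct$net_bp,
    mean_net_bp_per_line = a$indel_acct$mean_net_per_line,
    window = a$params$window, bootstrap_B = a$params$B,
    seed = a$params$seed
  )
  if (!is.null(a$ne)) {
    report$ne <- a$ne$ne
    report$ne_ci_low <- a$ne$ci_low
    report$ne_ci_high <- a$ne$ci_high
    report$theta <- a$ne$theta
  }
  report <- report[order(names(report))]
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    tsv <- tibble(
      statistic = names(report),
      value = vapply(report, function(v) format(v, digits = 15),
                     character(1))
    )
    readr::write_tsv(tsv, file.path(dir, "report.tsv"))
  }
  invisible(report)
}
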