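# Rate estimators, spectrum arithmetic, conditional rates, equilibrium GC,
# bias and Ts/Tv ratios, indel rates.

toy_lines <- function(n = 4, n_sites = 1e6, T_gen = 100) {
  tibble::tibble(
    line_id = sprintf("L%02d", seq_len(n)),
    lab = rep(c("L", "QS"), length.out = n),
    generations = T_gen,
    callable_sites = as.integer(n_sites),
    callable_AT_sites = as.integer(0.75 * n_sites),
    callable_GC_sites = as.integer(0.25 * n_sites)
  )
}

sub_row <- function(line, pos, ref, alt) {
  tibble::tibble(line_id = line, chrom = "chr1", pos = as.integer(pos),
                 ref = ref, alt = alt, mclass = "substitution",
                 indel_length = 0L)
}

test_that("per-line rate is m/(nT) with guarded inputs", {
  expect_equal(per_line_rate(0, 1e6, 100), 0)
  expect_equal(per_line_rate(2, 1e6, 100), 2e-8)
  expect_error(per_line_rate(1, 0, 10), "> 0")
  expect_error(per_line_rate(1, 10, 0), "> 0")
  expect_error(per_line_rate(-1, 10, 10), ">= 0")
})

test_that("experiment rate is the unweighted line mean with sd/sqrt(n) SE", {
  lines <- toy_lines(2)
  muts <- dplyr::bind_rows(sub_row("L01", 10, "A", "G"),
                           sub_row("L02", 20, "A", "G"))
  pl <- per_line_rates(lines, muts)
  est <- experiment_rate(pl)
  expect_equal(est$point, 1 / (1e6 * 100))
  expect_equal(est$se, 0)            # identical rates

  one <- experiment_rate(per_line_rates(toy_lines(1), sub_row("L01", 5, "A", "C")))
  expect_equal(one$point, 1e-8)
  expect_true(is.na(one$se))
})

test_that("rates are scale-consistent in T", {
  lines <- toy_lines(5)
  withr::with_seed(3, {
    muts <- dplyr::bind_rows(lapply(1:5, function(i) {
      sub_row(sprintf("L%02d", i), sample.int(1000, 1 + i), "A", "T")
    }))
  })
  pl1 <- per_line_rates(lines, muts)
  lines2 <- dplyr::mutate(lines, generations = generations * 2)
  pl2 <- per_line_rates(lines2, muts)
  expect_equal(pl2$rate_bs, pl1$rate_bs / 2)
  expect_equal(mean(pl2$rate_indel), mean(pl1$rate_indel) / 2)
})

test_that("spectrum counts conserve the substitution total", {
  fx <- small_experiment()
  spec <- spectrum_counts(fx$truth$mutations)
  expect_equal(sum(spec$count),
               sum(fx$truth$mutations$mclass == "substitution"))
  expect_equal(sum(spec$count[spec$type == "ts"]) +
                 sum(spec$count[spec$type == "tv"]), sum(spec$count))
})

test_that("Ts/Tv matches direct counts", {
  mk_spec <- function(counts) {
    tibble::tibble(
      class = c("AT_to_GC_ts", "AT_to_CG_tv", "AT_to_TA_tv",
                "GC_to_AT_ts", "GC_to_TA_tv", "GC_to_CG_tv"),
      count = counts,
      type = c("ts", "tv", "tv", "ts", "tv", "tv")
    )
  }
  # the observed 11 ts vs 26 tv regime
  expect_equal(round(ts_tv_ratio(mk_spec(c(4, 1, 13, 7, 9, 3))), 2), 0.42)
  # random expectation is 0.5
  expect_equal(ts_tv_ratio(mk_spec(c(6, 6, 6, 7, 7, 7))), 0.5)
  expect_equal(ts_tv_ratio(mk_spec(c(0, 5, 5, 0, 5, 5))), 0)
  expect_warning(inf_val <- ts_tv_ratio(mk_spec(c(3, 0, 0, 3, 0, 0))),
                 "infinite")
  expect_identical(inf_val, Inf)
})

test_that("conditional rates use GC-changing classes and site-generations", {
  lines <- toy_lines(2, n_sites = 1e6, T_gen = 100)
  # only the GC-conservative A:T->T:A class: both conditional rates 0
  muts <- dplyr::bind_rows(sub_row("L01", 1:3, "A", "T"))
  cr <- conditional_rates(spectrum_counts(muts), lines)
  expect_equal(cr$mu_ATtoGC, 0)
  expect_equal(cr$mu_GCtoAT, 0)

  # formula shape: 5 A/T->G/C changes (4 ts + 1 tv) over denominators
  # chosen to land on 0.44e-11
  m5 <- dplyr::bind_rows(sub_row("L01", 1:4, "A", "G"),
                         sub_row("L01", 5, "T", "G"))
  denom_target <- 5 / 0.44e-11
  lines5 <- tibble::tibble(
    line_id = "L01", generations = 1,
    callable_sites = denom_target,
    callable_AT_sites = denom_target, callable_GC_sites = 1
  )
  cr5 <- conditional_rates(spectrum_counts(m5), lines5)
  expect_equal(cr5$mu_ATtoGC * 1e11, 0.44, tolerance = 1e-6)
  expect_equal(cr5$m_ATtoGC, 5)
})

test_that("conditional rates are recovered from simulation", {
  cfg <- simulation_config(
    genome_length = 2e5, n_lines = 20, generations_per_line = 20,
    mu_bs = 1.5e-5, mu_indel = 0, mnm_fraction = 0, seed = 55
  )
  g <- generate_genome(cfg)
  tr <- simulate_ma_lines(g, cfg)
  cr <- conditional_rates(spectrum_counts(tr$mutations), tr$lines)
  # true conditional rates: class mass (w1+w2) of all events lands on
  # A/T sites, so the per-A/T-site rate is mu_bs * (w1+w2) * n / n_AT
  w <- cfg$spectrum_weights
  frac_at <- sum(tr$lines$callable_AT_sites * tr$lines$generations) /
    sum(tr$lines$callable_sites * tr$lines$generations)
  mu_at_true <- cfg$mu_bs * sum(w[1:2]) / frac_at
  mu_gc_true <- cfg$mu_bs * sum(w[4:5]) / (1 - frac_at)
  ci_at <- stats::poisson.test(cr$m_ATtoGC)$conf.int / cr$denom_AT
  ci_gc <- stats::poisson.test(cr$m_GCtoAT)$conf.int / cr$denom_GC
  expect_gte(mu_at_true, ci_at[1]); expect_lte(mu_at_true, ci_at[2])
  expect_gte(mu_gc_true, ci_gc[1]); expect_lte(mu_gc_true, ci_gc[2])
})

test_that("equilibrium GC follows the two conditional rates", {
  expect_equal(equilibrium_gc(0.44e-11, 4.36e-11), 0.44 / 4.8)
  expect_equal(round(100 * equilibrium_gc(0.44e-11, 4.36e-11), 1), 9.2)
  expect_equal(equilibrium_gc(0, 1e-11), 0)
  expect_equal(equilibrium_gc(3e-11, 3e-11), 0.5)
  expect_error(equilibrium_gc(0, 0), "zero")
  # complementarity
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- runif(1); b <- runif(1)
      expect_equal(equilibrium_gc(a, b) + equilibrium_gc(b, a), 1)
    }
  })
})

test_that("bias ratio and reciprocal", {
  expect_equal(bias_ratio(1e-11, 1e-11)$gc_bias, 1)
  br <- bias_ratio(0.44e-11, 4.36e-11)
  expect_equal(round(br$gc_bias, 3), 0.101)
  expect_equal(round(br$at_bias, 1), 9.9)
  expect_error(bias_ratio(1e-11, 0), "> 0")
})

test_that("indel rates split by class and compare labs", {
  lines <- toy_lines(6)
  zero <- suppressWarnings(indel_rates(lines, sub_row("L01", 5, "A", "C"),
                                       B = 50, seed = 1))
  expect_equal(zero$total$point, 0)
  expect_equal(zero$insertion$point, 0)
  expect_equal(zero$deletion$point, 0)

  # deletion fraction recovered within a binomial CI
  cfg <- simulation_config(
    genome_length = 1e5, n_lines = 10, generations_per_line = 20,
    mu_bs = 0, mu_indel = 2e-5, deletion_fraction = 0.818, seed = 66
  )
  g <- generate_genome(cfg)
  tr <- suppressWarnings(simulate_ma_lines(g, cfg))
  n_del <- sum(tr$mutations$mclass == "deletion")
  n_tot <- nrow(tr$mutations)
  ci <- stats::binom.test(n_del, n_tot)$conf.int
  expect_gte(0.818, ci[1]); expect_lte(0.818, ci[2])
  # a 4.5x deletion regime
  expect_gt(n_del / (n_tot - n_del), 3)

  ir <- indel_rates(tr$lines, tr$mutations, B = 200, seed = 2)
  expect_false(is.null(ir$lab_test))
  expect_equal(ir$total$point,
               mean(ir$per_line$rate_indel))
})

test_that("a 3.5-fold lab rate difference is detected by the Welch test", {
  # per-line Poisson counts at rates differing 3.5x, 19 + 18 lines
  reject <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      lines <- tibble::tibble(
        line_id = sprintf("L%02d", 1:37),
        lab = rep(c("L", "QS"), length.out = 37),
        generations = 20, callable_sites = 1e5
      )
      lam <- ifelse(lines$lab == "L", 3.5, 1) * 1.5e-6 *
        lines$callable_sites * lines$generations
      counts <- rpois(37, lam)
      muts <- tibble::tibble(
        line_id = rep(lines$line_id, counts),
        chrom = "chr1", pos = 1L, ref = "AT", alt = "A",
        mclass = "deletion", indel_length = 1L
      )
      ir <- suppressWarnings(indel_rates(lines, muts, B = 50, seed = s))
      ir$lab_test$p_value < 0.05
    })
  }, logical(1))
  expect_gte(sum(reject), 9)
})
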