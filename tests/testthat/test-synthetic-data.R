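# Forward simulator: genome composition, planted features, per-line
# mutation counts, MNM pairing, determinism of the written files.

test_that("config validation rejects impossible experiments", {
  expect_error(simulation_config(genome_length = 5000), "genome_length")
  expect_error(simulation_config(gc_content = 1.5), "gc_content")
  expect_error(simulation_config(generations_per_line = c(10, 20), n_lines = 3),
               "generations_per_line")
  expect_error(simulation_config(generations_per_line = 0), ">= 1")
  expect_error(simulation_config(ssr_target_fraction = 0.5, gene_fraction = 0.6),
               "infeasible")
  expect_error(simulation_config(spectrum_weights = rep(-1, 6)))
})

test_that("generated genome hits the target GC and SSR fraction", {
  cfg <- simulation_config(genome_length = 1e6, gc_content = 0.225,
                           ssr_target_fraction = 0.143, seed = 11)
  g <- generate_genome(cfg)
  stats <- reference_base_stats(g$sequences)
  expect_gte(stats$gc_fraction, 0.205)
  expect_lte(stats$gc_fraction, 0.245)

  covered <- sum(g$ssr_truth$end - g$ssr_truth$start)
  frac <- covered / sum(Biostrings::width(g$sequences))
  expect_gte(frac, 0.143 * 0.8)
  expect_lte(frac, 0.143 * 1.2)

  # genes: non-overlapping, length divisible by 3, ATG start on the coding
  # strand, internally consistent frame (no internal stop codons)
  genes <- g$genes
  expect_true(all((genes$end - genes$start) %% 3 == 0))
  by_chrom <- split(genes, genes$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  for (i in sample.int(nrow(genes), 10)) {
    r <- genes[i, ]
    s <- Biostrings::subseq(g$sequences[[r$chrom]], r$start + 1, r$end)
    if (r$strand == "-") s <- Biostrings::reverseComplement(s)
    aa <- as.character(Biostrings::translate(s))
    expect_identical(substr(aa, 1, 1), "M")
    # single terminal stop, none internal
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("ssr_target_fraction = 0 plants no tracts", {
  cfg <- simulation_config(genome_length = 2e4, ssr_target_fraction = 0,
                           gene_fraction = 0.3, n_lines = 2, seed = 5)
  g <- generate_genome(cfg)
  expect_identical(nrow(g$ssr_truth), 0L)
})

test_that("zero mutation rates give empty truth and zero event counts", {
  cfg <- simulation_config(genome_length = 1e4, mu_bs = 0, mu_indel = 0,
                           n_lines = 3, seed = 2)
  g <- generate_genome(cfg)
  tr <- simulate_ma_lines(g, cfg)
  expect_identical(nrow(tr$mutations), 0L)
  expect_true(all(tr$per_line_event_counts$n_events == 0))
})

test_that("saturating rates are refused", {
  cfg <- simulation_config(genome_length = 1e4, mu_bs = 0.1,
                           generations_per_line = 10, n_lines = 1, seed = 3)
  g <- generate_genome(cfg)
  expect_error(simulate_ma_lines(g, cfg), "saturation")
})

test_that("per-line substitution counts match the Poisson expectation", {
  # mu * n * T = 1e-6 * ~1e6 * 10 = ~10 expected per line over 50 lines
  cfg <- simulation_config(
    genome_length = 1e6, n_lines = 50, generations_per_line = 10,
    mu_bs = 1e-6, mu_indel = 0, mnm_fraction = 0, callable_fraction = 1,
    seed = 301
  )
  g <- generate_genome(cfg)
  tr <- simulate_ma_lines(g, cfg)
  per_line <- table(factor(tr$mutations$line_id,
                           levels = tr$lines$line_id))
  expected <- cfg$mu_bs * mean(tr$lines$callable_sites) * 10
  sem <- sqrt(expected / 50)
  expect_lt(abs(mean(per_line) - expected), 3 * sem)
})

test_that("the MNM pair fraction is recovered from truth labels", {
  cfg <- simulation_config(
    genome_length = 2e5, n_lines = 20, generations_per_line = 20,
    mu_bs = 1.5e-5, mu_indel = 0, mnm_fraction = 0.1, seed = 77
  )
  g <- generate_genome(cfg)
  tr <- simulate_ma_lines(g, cfg)
  ev <- dplyr::count(tr$mutations, event_id, name = "size")
  n_events <- nrow(ev)
  expect_gt(n_events, 800)
  frac_paired <- mean(ev$size == 2)
  ci <- stats::binom.test(sum(ev$size == 2), n_events)$conf.int
  # simulated pair fraction is slightly below mnm_fraction because a
  # partner can fail placement or collide; allow the CI to cover 0.1
  # within one collision-rate margin
  expect_lt(ci[1], 0.1)
  expect_gt(ci[2], 0.085)
})

test_that("spectrum class frequencies follow the configured weights", {
  cfg <- simulation_config(
    genome_length = 2e5, n_lines = 20, generations_per_line = 20,
    mu_bs = 1.5e-5, mu_indel = 0, mnm_fraction = 0, seed = 78
  )
  g <- generate_genome(cfg)
  tr <- simulate_ma_lines(g, cfg)
  expect_gt(nrow(tr$mutations), 500)
  spec <- spectrum_counts(tr$mutations)
  # realised class frequencies follow the configured weights; exact
  # binomial CIs per class, Bonferroni-sized so the six simultaneous
  # checks hold jointly at the 95% level
  p_exp <- cfg$spectrum_weights
  total <- sum(spec$count)
  for (i in 1:6) {
    ci <- stats::binom.test(spec$count[i], total,
                            conf.level = 1 - 0.05 / 6)$conf.int
    expect_gte(p_exp[i], ci[1])
    expect_lte(p_exp[i], ci[2])
  }
})

test_that("truth mutations respect the callable masks and reference", {
  fx <- small_experiment()
  tr <- fx$truth
  # every truth position inside its line's mask
  for (lid in unique(tr$mutations$line_id)) {
    m <- tr$mutations[tr$mutations$line_id == lid, ]
    mask <- tr$masks[tr$masks$line_id == lid, ]
    ok <- vapply(seq_len(nrow(m)), function(i) {
      any(mask$chrom == m$chrom[i] &
            mask$start < m$pos[i] & m$pos[i] <= mask$end)
    }, logical(1))
    expect_true(all(ok))
  }
  # REF strings match the reference
  ref <- fx$genome$sequences
  for (i in sample.int(nrow(tr$mutations), min(50, nrow(tr$mutations)))) {
    r <- tr$mutations[i, ]
    obs <- as.character(Biostrings::subseq(ref[[r$chrom]], r$pos,
                                           width = nchar(r$ref)))
    expect_identical(r$ref, obs)
  }
  # event accounting: MNM pairs collapse to one event
  ev <- dplyr::count(tr$mutations, line_id, event_id)
  agg <- dplyr::count(ev, line_id, name = "n_events")
  joined <- dplyr::left_join(tr$per_line_event_counts, agg, by = "line_id")
  joined$n_events.y[is.na(joined$n_events.y)] <- 0L
  expect_equal(joined$n_events.x, joined$n_events.y)
})

test_that("identical seed and config give byte-identical output files", {
  cfg <- simulation_config(genome_length = 2e4, n_lines = 3,
                           gene_fraction = 0.3, mu_bs = 5e-5,
                           mu_indel = 5e-5, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- generate_genome(cfg); t1 <- simulate_ma_lines(g1, cfg)
  write_ma_experiment(g1, t1, d1)
  g2 <- generate_genome(cfg); t2 <- simulate_ma_lines(g2, cfg)
  write_ma_experiment(g2, t2, d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})
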