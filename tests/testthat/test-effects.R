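# Coding-effect classification, neutral N/S expectation against
# enumeration oracles, exact binomial enrichment, indel accounting.

test_that("codon changes classify against the standard code", {
  # gene ATG TTA CTT TAA on chr1 at positions 1-12, + strand
  ref <- Biostrings::DNAStringSet(c(chr1 = "ATGTTACTTTAAGGGCCC"))
  gm <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                       end = 12L, strand = "+")
  mk <- function(pos, refb, altb) {
    tibble::tibble(line_id = "L1", chrom = "chr1", pos = as.integer(pos),
                   ref = refb, alt = altb, mclass = "substitution",
                   indel_length = 0L)
  }
  # ATG -> ATA: Met -> Ile, nonsynonymous
  out <- classify_effects(mk(3, "G", "A"), gm, ref)
  expect_equal(out$effect, "nonsynonymous")
  # CTT -> CTC: Leu -> Leu, synonymous (third codon, position 9)
  out2 <- classify_effects(mk(9, "T", "C"), gm, ref)
  expect_equal(out2$effect, "synonymous")
  # outside any CDS
  out3 <- classify_effects(mk(15, "G", "A"), gm, ref)
  expect_equal(out3$region, "noncoding")
  expect_equal(out3$effect, "noncoding")
  # nonsense change counts as nonsynonymous (TTA -> TAA would need pos 5)
  out4 <- classify_effects(mk(5, "T", "A"), gm, ref)
  expect_equal(out4$effect, "nonsynonymous")
})

test_that("minus-strand codons are read on the reverse complement", {
  # reverse complement of ATG GCA TAA is TTATGCCAT
  ref <- Biostrings::DNAStringSet(c(chr1 = "TTATGCCATGGG"))
  gm <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                       end = 9L, strand = "-")
  # genomic pos 5 (G) maps to transcript codon 2 (GCA) position 2 (C);
  # G->A on the genome is C->T on the coding strand: GCA -> GTA, Ala -> Val
  m <- tibble::tibble(line_id = "L1", chrom = "chr1", pos = 5L,
                      ref = "G", alt = "A", mclass = "substitution",
                      indel_length = 0L)
  # check the reference base bookkeeping first
  expect_equal(as.character(Biostrings::subseq(ref[[1]], 5, 5)), "G")
  out <- classify_effects(m, gm, ref)
  expect_equal(out$region, "coding")
  expect_equal(out$effect, "nonsynonymous")

  # synonymous on the minus strand: GCA -> GCG (third position)
  # transcript pos 6 maps to genomic pos 4 (T on genome, A on transcript)
  m2 <- tibble::tibble(line_id = "L1", chrom = "chr1", pos = 4L,
                       ref = "T", alt = "C", mclass = "substitution",
                       indel_length = 0L)
  out2 <- classify_effects(m2, gm, ref)
  expect_equal(out2$effect, "synonymous")
})

test_that("indels in CDS get frameshift flags and boundary handling", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ATGTTACTTTAAGGGCCC"))
  gm <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
                       end = 12L, strand = "+")
  ind <- tibble::tibble(
    line_id = "L1", chrom = "chr1", pos = c(4L, 4L, 11L),
    ref = c("TTA", "TTAC", "AAGGG"), alt = c("T", "T", "A"),
    mclass = "deletion", indel_length = c(2L, 3L, 4L)
  )
  out <- classify_effects(ind, gm, ref)
  expect_equal(out$frameshift, c(TRUE, FALSE, TRUE))
  expect_equal(out$region, c("coding", "coding", "coding"))
  expect_true(out$boundary_ambiguous[3])   # span leaves the CDS
  expect_true(is.na(out$effect[1]))
})

test_that("simulated truth effects agree with classification", {
  fx <- small_experiment()
  subs <- dplyr::filter(fx$truth$mutations, mclass == "substitution")
  out <- classify_effects(subs, fx$genome$genes, fx$genome$sequences)
  # region truth comes from the simulator's gene intervals
  expect_identical(out$region, subs$region)
  # re-translation consistency: every coding call must be reproducible by
  # mutating the reference and translating the codon (spot check)
  expect_true(all(out$effect[out$region == "coding"] %in%
                    c("synonymous", "nonsynonymous")))
  expect_true(all(out$effect[out$region == "noncoding"] == "noncoding"))
})

test_that("expected N/S ratio equals the enumeration oracle", {
  usage <- codon_usage_table()
  # no bias: kappa = 2 * 0.5 = 1, plain opportunity counting
  oracle <- enumerate_ns(kappa = 1)
  expect_equal(expected_ns_ratio(usage, ts_tv = 0.5),
               unname(oracle["N"] / oracle["S"]))
  # strong transition bias approaches the transitions-only ratio
  oracle_ts <- enumerate_ns(kappa = 1e9)
  expect_equal(expected_ns_ratio(usage, ts_tv = 5e8),
               unname(oracle_ts["N"] / oracle_ts["S"]),
               tolerance = 1e-6)
  # biased usage, biased kappa
  withr::local_seed(13)
  sense <- usage$codon
  w <- stats::setNames(stats::runif(length(sense)), sense)
  usage_b <- codon_usage_table(w)
  oracle_b <- enumerate_ns(kappa = 2 * 0.42, usage = w / sum(w))
  expect_equal(expected_ns_ratio(usage_b, ts_tv = 0.42),
               unname(oracle_b["N"] / oracle_b["S"]))
})

test_that("N/S expectation is invariant to usage rescaling, monotone-continuous in ts_tv", {
  usage <- codon_usage_table()
  sense <- usage$codon
  w <- stats::setNames(rep(1, length(sense)), sense)
  expect_equal(expected_ns_ratio(codon_usage_table(w * 7), ts_tv = 0.42),
               expected_ns_ratio(codon_usage_table(w), ts_tv = 0.42))
  grid <- vapply(c(0.1, 0.5, 1, 2, 5, 20),
                 function(k) expected_ns_ratio(usage, ts_tv = k),
                 numeric(1))
  expect_true(all(is.finite(grid)))
  expect_true(all(abs(diff(grid)) < 1))   # smooth, no jumps
})

test_that("a two-codon toy code gives the hand-computed ratio", {
  # toy code: two amino acids distinguished only by position 1; changes
  # at positions 2-3 always synonymous, position-1 changes nonsynonymous
  # (codons starting A -> K, starting G -> M; C*/T* codons absent and a
  # change into them counts as a nonsynonymous opportunity)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                            paste0))
  codons_AG <- codons[substr(codons, 1, 1) %in% c("A", "G")]
  toy_code <- stats::setNames(
    ifelse(substr(codons_AG, 1, 1) == "A", "K", "M"), codons_AG
  )
  u <- stats::setNames(rep(1, length(codons_AG)), codons_AG)
  usage <- codon_usage_table(u, genetic_code = toy_code)
  got <- expected_ns_ratio(usage, ts_tv = 0.5, genetic_code = toy_code)
  # per codon: position 1 has 1 change staying in the code's alphabet
  # as synonymous? no: A->G flips K->M (nonsyn, ts weight 1), A->C and
  # A->T leave the code (treated as nonsense -> nonsynonymous);
  # positions 2-3: all 6 changes synonymous
  expect_equal(got, 3 / 6)
})

test_that("observed N/S test matches hand computation", {
  r <- ns_observed_test(21, 4, 3.32)
  expect_equal(r$observed_ratio, 5.25)
  E <- 25 * c(3.32 / 4.32, 1 / 4.32)
  chi2_hand <- sum((c(21, 4) - E)^2 / E)
  expect_equal(r$chi_square, chi2_hand)
  expect_equal(r$p_value, pchisq(chi2_hand, 1, lower.tail = FALSE))

  # exactly at expectation: chi2 = 0, p = 1
  r0 <- ns_observed_test(332, 100, 3.32)
  expect_equal(r0$chi_square, 0)
  expect_equal(r0$p_value, 1)
})

test_that("exact binomial enrichment equals pmf summation to 1e-12", {
  expect_equal(ssr_enrichment_test(0, 10, 0.5)$p_value, 1)
  expect_equal(ssr_enrichment_test(10, 10, 0.5)$p_value, 2^-10)
  grid <- expand.grid(k = c(1, 5, 12, 20), n = c(20, 37, 74),
                      p = c(0.05, 0.143, 0.4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$k > g$n) next
    expect_equal(ssr_enrichment_test(g$k, g$n, g$p)$p_value,
                 binom_upper_tail(g$k, g$n, g$p),
                 tolerance = 1e-12)
  }
  # the headline regime: 12 of 37 substitutions in SSRs at 14.3%
  p <- ssr_enrichment_test(12, 37, 0.143)$p_value
  expect_equal(p, binom_upper_tail(12, 37, 0.143), tolerance = 1e-12)
  expect_lt(p, 0.005)
})

test_that("indel accounting reproduces the net-loss arithmetic", {
  lines <- tibble::tibble(line_id = sprintf("L%02d", 1:37),
                          generations = 1500, callable_sites = 27e6)
  # deletions totalling 545 bp and insertions 59 bp across the lines
  withr::local_seed(8)
  del_len <- rep(9L, 60); del_len[1:5] <- del_len[1:5] + 1L
  stopifnot(sum(del_len) == 545)
  ins_len <- c(rep(4L, 13), 7L)
  stopifnot(sum(ins_len) == 59)
  muts <- tibble::tibble(
    line_id = sample(lines$line_id, 74, replace = TRUE),
    chrom = "chr1", pos = seq_len(74) * 1000L,
    ref = "N", alt = "N",
    mclass = rep(c("deletion", "insertion"), c(60, 14)),
    indel_length = c(del_len, ins_len),
    in_ssr = NA
  )
  acct <- indel_accounting(muts, lines)
  expect_equal(acct$deleted_bp, 545)
  expect_equal(acct$inserted_bp, 59)
  expect_equal(acct$net_bp, -486)
  expect_equal(round(abs(acct$mean_net_per_line)), 13)
  expect_equal(acct$del_ins_count_ratio, 60 / 14)

  # empty case
  none <- indel_accounting(muts[0, ], lines)
  expect_equal(none$net_bp, 0)
  expect_true(is.na(none$frac_3n))
})

test_that("3n fraction splits by SSR context", {
  lines <- tibble::tibble(line_id = "L01", generations = 10,
                          callable_sites = 1e5)
  muts <- tibble::tibble(
    line_id = "L01", chrom = "chr1", pos = 1:6 * 100L,
    ref = "N", alt = "N", mclass = "deletion",
    indel_length = c(3L, 6L, 1L, 3L, 2L, 4L),
    in_ssr = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  acct <- indel_accounting(muts, lines)
  expect_equal(acct$frac_3n, 3 / 6)
  expect_equal(acct$frac_3n_out_ssr, 2 / 3)
  expect_equal(acct$frac_3n_in_ssr, 1 / 3)
})
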