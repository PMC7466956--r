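# Coding-effect classification and neutral expectations. Substitutions in
# CDS are called synonymous/nonsynonymous by mutating the codon in place
# and translating; the neutral nonsynonymous/synonymous ratio weights
# every single-base codon change by codon usage and the observed Ts/Tv
# bias.

#' Construct a codon usage table
#'
#' @param freq Named numeric vector (names = codons, e.g. `"ATG"`);
#'   frequencies are normalised over sense codons. `NULL` gives uniform
#'   usage over the 61 sense codons of the standard code.
#' @param genetic_code Named character vector mapping codons to amino
#'   acids (`"*"` = stop); default `Biostrings::GENETIC_CODE`.
#' @return A `"codon_usage"` tibble: `codon`, `aa`, `freq` (sense codons
#'   only, summing to 1).
#' @export
codon_usage_table <- function(freq = NULL,
                              genetic_code = Biostrings::GENETIC_CODE) {
  sense <- names(genetic_code)[genetic_code != "*"]
  if (is.null(freq)) {
    freq <- setNames(rep(1 / length(sense), length(sense)), sense)
  }
  names(freq) <- toupper(gsub("U", "T", names(freq)))
  bad <- setdiff(names(freq), names(genetic_code))
  if (length(bad) > 0) abort(paste0("unknown codon: ", bad[1]))
  stop_usage <- sum(freq[setdiff(names(freq), sense)], na.rm = TRUE)
  if (stop_usage > 1e-9) {
    warn("nonzero stop-codon usage ignored (stop codons are excluded from opportunity counting)")
  }
  freq <- freq[names(freq) %in% sense]
  if (sum(freq) <= 0) abort("codon usage sums to zero over sense codons")
  out <- tibble(
    codon = sense,
    aa = unname(genetic_code[sense]),
    freq = unname(freq[sense])
  )
  out$freq[is.na(out$freq)] <- 0
  out$freq <- out$freq / sum(out$freq)
  structure(out, class = c("codon_usage", class(out)))
}

#' Read a codon usage table from TSV
#'
#' Expects columns `codon` and `frequency` (relative usage; normalised on
#' read).
#'
#' @param tsv_path Path to the TSV.
#' @inheritParams codon_usage_table
#' @return A `"codon_usage"` tibble.
#' @export
read_codon_usage <- function(tsv_path,
                             genetic_code = Biostrings::GENETIC_CODE) {
  tab <- readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("codon", "frequency") %in% names(tab))) {
    abort("codon usage TSV needs columns `codon` and `frequency`")
  }
  codon_usage_table(setNames(tab$frequency, tab$codon),
                    genetic_code = genetic_code)
}

# per-gene CDS sequence and a genomic-position -> transcript-position map
.gene_cds_index <- function(gene_models, reference) {
  genes <- split(gene_models, gene_models$gene_id)
  lapply(genes, function(g) {
    g <- arrange(g, .data$start)
    seqs <- map(seq_len(nrow(g)), function(i) {
      as.character(Biostrings::subseq(reference[[g$chrom[i]]],
                                      start = g$start[i] + 1L, end = g$end[i]))
    })
    cds_fwd <- paste(unlist(seqs), collapse = "")   # genomic orientation
    minus <- g$strand[1] == "-"
    cds <- if (minus) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_fwd)))
    } else {
      cds_fwd
    }
    list(g = g, cds = cds, minus = minus,
         seg_offsets = cumsum(c(0L, head(g$end - g$start, -1L))),
         total = sum(g$end - g$start))
  })
}

# transcript coordinate (1-based, 5'->3') of genomic pos within gene gi
.transcript_pos <- function(gi, chrom, pos) {
  g <- gi$g
  seg <- which(g$chrom == chrom & pos > g$start & pos <= g$end)
  if (length(seg) == 0) return(NA_integer_)
  fwd <- gi$seg_offsets[seg] + (pos - g$start[seg])
  if (gi$minus) gi$total - fwd + 1L else fwd
}

#' Classify mutations by genomic context and coding effect
#'
#' Substitutions inside a CDS are synonymous iff the mutated codon
#' translates to the same amino acid (on the coding strand). Indels
#' inside a CDS are flagged frameshift when their length is not a
#' multiple of 3. Deletions whose span crosses a CDS boundary are
#' classified by their anchored base and flagged `boundary_ambiguous`.
#'
#' @param mutations A mutation tibble.
#' @param gene_models A [read_gene_models()] tibble (or the simulator's
#'   gene truth with a `strand` column).
#' @param reference A [read_reference()] result.
#' @param genetic_code Codon -> amino-acid map (default standard code).
#' @return `mutations` with `region` (`coding`/`noncoding`), `effect`
#'   (`synonymous`/`nonsynonymous`/`noncoding`, `NA` for indels),
#'   `frameshift` (indels in CDS) and `boundary_ambiguous` columns.
#' @export
classify_effects <- function(mutations, gene_models, reference,
                             genetic_code = Biostrings::GENETIC_CODE) {
  .assert_mutations(mutations)
  if (!"segment" %in% names(gene_models)) {
    gene_models <- mutate(gene_models, segment = 1L)
  }
  if (nrow(mutations) == 0) {
    return(mutate(mutations, frameshift = logical(0),
                  boundary_ambiguous = logical(0)))
  }
  idx <- .gene_cds_index(gene_models, reference)

  region <- character(nrow(mutations))
  effect <- rep(NA_character_, nrow(mutations))
  frameshift <- rep(NA, nrow(mutations))
  ambiguous <- rep(FALSE, nrow(mutations))

  # gene lookup by chromosome for speed
  gm_by_chrom <- split(gene_models, gene_models$chrom)

  for (i in seq_len(nrow(mutations))) {
    chrom <- mutations$chrom[i]; pos <- mutations$pos[i]
    gm <- gm_by_chrom[[chrom]]
    hit <- if (is.null(gm)) integer(0) else {
      which(pos > gm$start & pos <= gm$end)
    }
    if (length(hit) == 0) {
      region[i] <- "noncoding"
      effect[i] <- if (mutations$mclass[i] == "substitution") "noncoding" else NA_character_
      next
    }
    gid <- gm$gene_id[hit[1]]
    gi <- idx[[gid]]
    region[i] <- "coding"
    if (mutations$mclass[i] == "substitution") {
      tp <- .transcript_pos(gi, chrom, pos)
      codon_i <- (tp - 1L) %/% 3L + 1L
      off <- (tp - 1L) %% 3L + 1L
      codon <- substr(gi$cds, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
      alt_base <- mutations$alt[i]
      if (gi$minus) {
        alt_base <- chartr("ACGT", "TGCA", alt_base)
      }
      mut_codon <- codon
      substr(mut_codon, off, off) <- alt_base
      aa0 <- genetic_code[[codon]]
      aa1 <- genetic_code[[mut_codon]]
      effect[i] <- if (identical(aa0, aa1)) "synonymous" else "nonsynonymous"
    } else {
      len <- mutations$indel_length[i]
      frameshift[i] <- (len %% 3L) != 0L
      if (mutations$mclass[i] == "deletion") {
        # span leaving the CDS interval -> ambiguous boundary call
        gseg <- gi$g[gi$g$chrom == chrom & pos > gi$g$start & pos <= gi$g$end, ]
        if (nrow(gseg) == 1 && pos + len > gseg$end) ambiguous[i] <- TRUE
      }
    }
  }
  mutations$region <- region
  mutations$effect <- effect
  mutations$frameshift <- frameshift
  mutations$boundary_ambiguous <- ambiguous
  mutations
}

#' Neutral expectation for the nonsynonymous/synonymous ratio
#'
#' Enumerates all nine single-base changes of every sense codon, weights
#' each by the codon's usage and by `kappa = 2 * ts_tv` for transitions
#' versus 1 for each transversion direction (so the implied pooled Ts/Tv
#' equals the input), counts changes to stop codons as nonsynonymous, and
#' returns the weighted nonsynonymous over synonymous opportunity ratio.
#' Alternatively a six-class spectrum weighting can be supplied; each
#' change is then weighted by its strand-symmetric class weight.
#'
#' @param codon_usage A [codon_usage_table()].
#' @param ts_tv Observed transition/transversion ratio (> 0). Ignored
#'   when `spectrum_weights` is given.
#' @param spectrum_weights Optional named 6-vector of class weights (see
#'   [spectrum_counts()] for class names).
#' @param genetic_code Codon -> amino-acid map.
#' @return Expected nonsynonymous/synonymous ratio under neutrality.
#' @export
#' @examples
#' expected_ns_ratio(codon_usage_table(), ts_tv = 0.5)
expected_ns_ratio <- function(codon_usage, ts_tv = NULL,
                              spectrum_weights = NULL,
                              genetic_code = Biostrings::GENETIC_CODE) {
  stopifnot(inherits(codon_usage, "codon_usage"))
  if (is.null(spectrum_weights)) {
    if (is.null(ts_tv) || ts_tv <= 0) abort("ts_tv must be > 0")
    kappa <- 2 * ts_tv
  } else {
    if (!all(SPECTRUM_CLASSES %in% names(spectrum_weights))) {
      abort("spectrum_weights must be named with the six class labels")
    }
  }
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  bases <- c("A", "C", "G", "T")
  W_N <- 0; W_S <- 0
  for (r in seq_len(nrow(codon_usage))) {
    codon <- codon_usage$codon[r]
    u <- codon_usage$freq[r]
    if (u == 0) next
    aa0 <- codon_usage$aa[r]
    for (p in 1:3) {
      refb <- substr(codon, p, p)
      for (altb in setdiff(bases, refb)) {
        w <- if (is.null(spectrum_weights)) {
          if (identical(transitions[[refb]], altb)) kappa else 1
        } else {
          unname(spectrum_weights[substitution_class(refb, altb)])
        }
        mut <- codon
        substr(mut, p, p) <- altb
        # stop codons and codons absent from a reduced code count as
        # nonsynonymous opportunities
        aa1 <- unname(genetic_code[mut])
        if (identical(aa1, aa0)) W_S <- W_S + u * w else W_N <- W_N + u * w
      }
    }
  }
  if (W_S == 0) abort("no synonymous opportunity (degenerate code/usage)")
  W_N / W_S
}

#' Observed vs expected nonsynonymous/synonymous test
#'
#' One-degree-of-freedom chi-square comparing observed (N, S) counts to
#' the expected proportions `(R/(1+R), 1/(1+R))` where `R` is the neutral
#' expected ratio.
#'
#' @param n_nonsyn,n_syn Observed counts.
#' @param expected_ratio Neutral expected N/S ratio `R`.
#' @return Tibble: `observed_ratio`, `expected_ratio`, `chi_square`,
#'   `df`, `p_value`.
#' @export
#' @examples
#' ns_observed_test(21, 4, 3.32)
ns_observed_test <- function(n_nonsyn, n_syn, expected_ratio) {
  total <- n_nonsyn + n_syn
  if (total < 1) abort("need at least one classified substitution")
  R <- expected_ratio
  expected <- total * c(R / (1 + R), 1 / (1 + R))
  observed <- c(n_nonsyn, n_syn)
  chi2 <- sum((observed - expected)^2 / expected)
  tibble(
    observed_ratio = n_nonsyn / n_syn,
    expected_ratio = R,
    chi_square = chi2, df = 1L,
    p_value = pchisq(chi2, 1L, lower.tail = FALSE)
  )
}

#' Exact binomial SSR enrichment test
#'
#' Upper-tail exact binomial probability `P(X >= k | n, ssr_fraction)`
#' that at least `k` of `n` mutations fall in SSRs when the callable
#' genome fraction in SSRs is `ssr_fraction`.
#'
#' @param k_in_ssr Mutations observed inside SSR loci.
#' @param n_total Total mutations.
#' @param ssr_fraction Callable-masked SSR genome fraction (in (0, 1)).
#' @return Tibble: `k`, `n`, `ssr_fraction`, `observed_fraction`,
#'   `p_value` (one-sided, enrichment).
#' @export
#' @examples
#' ssr_enrichment_test(12, 37, 0.143)
ssr_enrichment_test <- function(k_in_ssr, n_total, ssr_fraction) {
  stopifnot(k_in_ssr >= 0, k_in_ssr <= n_total,
            ssr_fraction > 0, ssr_fraction < 1)
  p <- if (k_in_ssr == 0) {
    1
  } else {
    binom.test(k_in_ssr, n_total, ssr_fraction,
               alternative = "greater")$p.value
  }
  tibble(k = k_in_ssr, n = n_total, ssr_fraction = ssr_fraction,
         observed_fraction = k_in_ssr / n_total, p_value = p)
}

#' Indel size accounting
#'
#' Total inserted and deleted base pairs, the signed net change, the
#' per-line mean net change with its SE, deletion:insertion ratios by
#' count and by bp, and the fraction of indels with length divisible by 3
#' (overall and split by SSR context when the `in_ssr` column is set).
#'
#' @param mutations A mutation tibble.
#' @param lines Lines tibble (defines the per-line denominator, including
#'   lines with no indels).
#' @return A list of class `"indel_accounting"` with fields
#'   `inserted_bp`, `deleted_bp`, `net_bp`, `per_line_net` (tibble),
#'   `mean_net_per_line`, `se_net_per_line`, `del_ins_count_ratio`,
#'   `del_ins_bp_ratio`, `frac_3n`, `frac_3n_in_ssr`,
#'   `frac_3n_out_ssr`, `n_insertions`, `n_deletions`.
#' @export
indel_accounting <- function(mutations, lines) {
  .assert_mutations(mutations)
  ind <- filter(mutations, .data$mclass %in% c("insertion", "deletion"))
  ins_bp <- sum(ind$indel_length[ind$mclass == "insertion"])
  del_bp <- sum(ind$indel_length[ind$mclass == "deletion"])
  n_ins <- sum(ind$mclass == "insertion")
  n_del <- sum(ind$mclass == "deletion")

  per_line <- lines %>%
    select("line_id") %>%
    left_join(
      ind %>%
        group_by(.data$line_id) %>%
        summarise(
          net_bp = sum(if_else(.data$mclass == "insertion",
                               .data$indel_length, -.data$indel_length)),
          .groups = "drop"
        ),
      by = "line_id"
    ) %>%
    mutate(net_bp = dplyr::coalesce(.data$net_bp, 0L))

  nl <- nrow(per_line)
  frac3 <- function(x) if (length(x) == 0) NA_real_ else mean(x %% 3L == 0L)
  has_ssr <- "in_ssr" %in% names(ind) && !all(is.na(ind$in_ssr))
  structure(
    list(
      inserted_bp = ins_bp, deleted_bp = del_bp, net_bp = ins_bp - del_bp,
      per_line_net = per_line,
      mean_net_per_line = mean(per_line$net_bp),
      se_net_per_line = if (nl >= 2) sd(per_line$net_bp) / sqrt(nl) else NA_real_,
      del_ins_count_ratio = if (n_ins > 0) n_del / n_ins else NA_real_,
      del_ins_bp_ratio = if (ins_bp > 0) del_bp / ins_bp else NA_real_,
      frac_3n = frac3(ind$indel_length),
      frac_3n_in_ssr = if (has_ssr) frac3(ind$indel_length[ind$in_ssr %in% TRUE]) else NA_real_,
      frac_3n_out_ssr = if (has_ssr) frac3(ind$indel_length[ind$in_ssr %in% FALSE]) else NA_real_,
      n_insertions = n_ins, n_deletions = n_del
    ),
    class = "indel_accounting"
  )
}

#' @export
print.indel_accounting <- function(x, ...) {
  cat(sprintf(
    "<indel_accounting> %d deletions (%d bp) vs %d insertions (%d bp): net %+d bp (%.1f bp/line, SE %.2g)\n",
    x$n_deletions, x$deleted_bp, x$n_insertions, x$inserted_bp,
    x$net_bp, x$mean_net_per_line, x$se_net_per_line
  ))
  invisible(x)
}

#' Summary of functional-effect counts
#'
#' @param mutations A classified mutation tibble (after
#'   [classify_effects()] and [annotate_variants_ssr()]).
#' @return One-row tibble with the Table-style counts: substitutions by
#'   effect, indels by region, in-SSR counts, and observed N/S ratio.
#' @export
effect_summary <- function(mutations) {
  subs <- filter(mutations, .data$mclass == "substitution")
  ind <- filter(mutations, .data$mclass != "substitution")
  tibble(
    n_substitutions = nrow(subs),
    n_synonymous = sum(subs$effect %in% "synonymous"),
    n_nonsynonymous = sum(subs$effect %in% "nonsynonymous"),
    n_noncoding_subs = sum(subs$effect %in% "noncoding"),
    n_indels = nrow(ind),
    n_coding_indels = sum(ind$region %in% "coding"),
    n_noncoding_indels = sum(ind$region %in% "noncoding"),
    n_subs_in_ssr = sum(subs$in_ssr %in% TRUE),
    n_indels_in_ssr = sum(ind$in_ssr %in% TRUE),
    observed_ns_ratio = n_nonsynonymous / n_synonymous
  )
}
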