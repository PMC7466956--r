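#' Configuration for a synthetic mutation-accumulation experiment
#'
#' Bundles every knob of the forward simulator. The defaults emulate the
#' genome and mutational regime of an AT-rich, microsatellite-dense social
#' amoeba: ~77% AT, ~14% of sites in simple sequence repeats (SSRs) with
#' repeat units biased toward 1, 3 and 6 bp, a deletion-biased indel process
#' elevated inside SSR tracts, a transversion-heavy substitution spectrum
#' with a strong G/C -> A/T bias, and a small fraction of substitution events
#' arriving as multinucleotide pairs within 50 bp. Rates default to a
#' scaled-up regime (rate x genome length x generations of the same order as
#' the real experiment's per-line mutation counts) so that a 1 Mb toy genome
#' yields informative per-line counts; set `mu_bs = 2.47e-11` etc. with a
#' full-size genome and ~1500 generations to mimic the original scale.
#'
#' @param genome_length Total genome size in bp (>= 10000).
#' @param gc_content Target GC fraction in `[0, 1]`.
#' @param n_chromosomes Number of chromosomes (genome split evenly).
#' @param ssr_target_fraction Fraction of the genome to cover with planted
#'   SSR tracts.
#' @param ssr_unit_weights Ten nonnegative weights over repeat-unit lengths
#'   1-10 bp.
#' @param gene_fraction Fraction of the genome inside protein-coding genes.
#' @param n_lines Number of MA lines.
#' @param generations_per_line Generations elapsed per line (scalar or
#'   length-`n_lines` vector), all >= 1.
#' @param callable_fraction Fraction of the genome callable in each line.
#' @param mu_bs Base-substitution rate per site per generation.
#' @param spectrum_weights Six nonnegative weights over the substitution
#'   classes, in the order of [spectrum_counts()] rows: A:T->G:C ts,
#'   A:T->C:G tv, A:T->T:A tv, G:C->A:T ts, G:C->T:A tv, G:C->C:G tv.
#' @param mu_indel Indel rate per site per generation (outside SSRs).
#' @param deletion_fraction Fraction of indels that are deletions.
#' @param indel_length_distribution Thirty nonnegative weights over indel
#'   lengths 1-30 bp (used outside SSR tracts; slippage indels inside a
#'   tract add or remove one repeat unit).
#' @param ssr_slippage_multiplier Indel-rate multiplier (>= 1) inside SSRs.
#' @param mnm_fraction Fraction of substitution events that spawn a second,
#'   paired substitution within +/- 50 bp on the same line.
#' @param seed Integer seed; every simulator call is a pure function of the
#'   config, so identical configs give byte-identical output files.
#'
#' @return A list of class `"simulation_config"`.
#' @export
#' @examples
#' cfg <- simulation_config(genome_length = 5e4, n_lines = 5, seed = 1)
#' cfg$gc_content
simulation_config <- function(genome_length = 1e6,
                              gc_content = 0.225,
                              n_chromosomes = 2,
                              ssr_target_fraction = 0.143,
                              ssr_unit_weights = c(3, 1, 3, 1, 1, 3,
                                                   0.5, 0.5, 0.5, 0.5),
                              gene_fraction = 0.62,
                              n_lines = 37,
                              generations_per_line = 20,
                              callable_fraction = 0.813,
                              mu_bs = 2.5e-6,
                              spectrum_weights = c(4, 1, 13, 7, 9, 3),
                              mu_indel = 5e-6,
                              deletion_fraction = 0.818,
                              indel_length_distribution = 0.85^(0:29),
                              ssr_slippage_multiplier = 3,
                              mnm_fraction = 0.12,
                              seed = 1L) {
  stopifnot(
    length(genome_length) == 1, genome_length >= 10000,
    length(gc_content) == 1, gc_content >= 0, gc_content <= 1,
    n_chromosomes >= 1,
    ssr_target_fraction >= 0, ssr_target_fraction <= 1,
    length(ssr_unit_weights) == 10, all(ssr_unit_weights >= 0),
    sum(ssr_unit_weights) > 0,
    gene_fraction >= 0, gene_fraction <= 1,
    n_lines >= 1,
    callable_fraction > 0, callable_fraction <= 1,
    mu_bs >= 0,
    length(spectrum_weights) == 6, all(spectrum_weights >= 0),
    sum(spectrum_weights) > 0,
    mu_indel >= 0,
    deletion_fraction >= 0, deletion_fraction <= 1,
    length(indel_length_distribution) == 30,
    all(indel_length_distribution >= 0),
    sum(indel_length_distribution) > 0,
    ssr_slippage_multiplier >= 1,
    mnm_fraction >= 0, mnm_fraction <= 1,
    length(seed) == 1, is.finite(seed)
  )
  if (length(generations_per_line) == 1) {
    generations_per_line <- rep(generations_per_line, n_lines)
  }
  if (length(generations_per_line) != n_lines) {
    abort("generations_per_line must be scalar or length n_lines")
  }
  if (any(generations_per_line < 1)) {
    abort("generations_per_line must all be >= 1")
  }
  if (ssr_target_fraction + gene_fraction > 0.95) {
    abort(paste0(
      "infeasible config: ssr_target_fraction + gene_fraction = ",
      ssr_target_fraction + gene_fraction,
      " leaves too little intergenic background (constraint: sum <= 0.95)"
    ))
  }
  cfg <- list(
    genome_length = as.numeric(genome_length),
    gc_content = gc_content,
    n_chromosomes = as.integer(n_chromosomes),
    ssr_target_fraction = ssr_target_fraction,
    ssr_unit_weights = ssr_unit_weights / sum(ssr_unit_weights),
    gene_fraction = gene_fraction,
    n_lines = as.integer(n_lines),
    generations_per_line = as.numeric(generations_per_line),
    callable_fraction = callable_fraction,
    mu_bs = mu_bs,
    spectrum_weights = spectrum_weights / sum(spectrum_weights),
    mu_indel = mu_indel,
    deletion_fraction = deletion_fraction,
    indel_length_distribution =
      indel_length_distribution / sum(indel_length_distribution),
    ssr_slippage_multiplier = ssr_slippage_multiplier,
    mnm_fraction = mnm_fraction,
    seed = as.integer(seed)
  )
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf(
    "  genome: %.3g bp, %d chromosome(s), GC %.3f, SSR target %.3f, genes %.3f\n",
    x$genome_length, x$n_chromosomes, x$gc_content,
    x$ssr_target_fraction, x$gene_fraction
  ))
  cat(sprintf(
    "  lines: %d, generations %s, callable %.3f\n",
    x$n_lines, paste(range(x$generations_per_line), collapse = "-"),
    x$callable_fraction
  ))
  cat(sprintf(
    "  rates: mu_bs %.3g, mu_indel %.3g (x%.1f in SSRs), del frac %.3f, MNM frac %.3f\n",
    x$mu_bs, x$mu_indel, x$ssr_slippage_multiplier,
    x$deletion_fraction, x$mnm_fraction
  ))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
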