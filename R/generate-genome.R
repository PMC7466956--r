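# Forward simulation of the reference genome: an i.i.d. background at the
# target GC, with protein-coding genes and perfect tandem-repeat (SSR)
# tracts planted in disjoint intervals. All coordinates in the returned
# truth tables are 0-based half-open (BED convention); GFF export converts.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# iid bases at a target GC fraction
.random_bases <- function(n, gc) {
  if (n == 0) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# gene body: ATG + sense codons at ~target GC + one stop codon; length 3k
.gene_sequence <- function(len, gc) {
  stopifnot(len %% 3 == 0, len >= 9)
  n_inner <- len / 3 - 2
  codons <- character(n_inner)
  if (n_inner > 0) {
    b <- matrix(.random_bases(3 * n_inner, gc), ncol = 3)
    codons <- paste0(b[, 1], b[, 2], b[, 3])
    bad <- codons %in% STOP_CODONS
    while (any(bad)) {
      k <- sum(bad)
      b <- matrix(.random_bases(3 * k, gc), ncol = 3)
      codons[bad] <- paste0(b[, 1], b[, 2], b[, 3])
      bad <- codons %in% STOP_CODONS
    }
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1))
}

# lexicographically smallest rotation of a repeat unit
.canonical_rotation <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n == 1) return(m)
    rot <- vapply(seq_len(n), function(i) {
      paste0(substr(m, i, n), substr(m, 1, i - 1))
    }, character(1))
    min(rot)
  }, character(1), USE.NAMES = FALSE)
}

# a repeat unit of length u at ~target GC whose minimal period is u
.ssr_motif <- function(u, gc) {
  repeat {
    m <- paste(.random_bases(u, gc), collapse = "")
    if (u == 1) return(m)
    # reject units that are themselves periodic (e.g. "ATAT" as a 4-mer)
    periodic <- any(vapply(seq_len(u - 1), function(p) {
      if (u %% p != 0) return(FALSE)
      identical(strrep(substr(m, 1, p), u / p), m)
    }, logical(1)))
    if (!periodic) return(m)
  }
}

# place n_feat intervals of the given lengths uniformly without overlap
# inside [1, L], each separated by >= gap bp; returns start positions
# (1-based) or NULL if it fails after max_tries rounds
.place_intervals <- function(lengths, L, gap = 2L, max_tries = 200L) {
  if (length(lengths) == 0) return(integer(0))
  total <- sum(lengths + gap)
  if (total > L) return(NULL)
  # classic "stars and bars": drop the lengths into the free space
  free <- L - total
  for (i in seq_len(max_tries)) {
    cuts <- sort(sample.int(free + 1L, length(lengths), replace = TRUE)) - 1L
    starts <- cuts + cumsum(c(0L, head(lengths + gap, -1L))) + 1L
    if (all(starts + lengths - 1L <= L)) return(starts)
  }
  NULL
}

#' Generate a synthetic reference genome with planted genes and SSR tracts
#'
#' Draws an i.i.d. background at the configured GC content, then plants
#' non-overlapping protein-coding genes (length divisible by 3, starting
#' with ATG, no internal stop codons, random strand) and perfect tandem
#' repeat tracts. Repeat unit lengths are drawn from
#' `config$ssr_unit_weights` (1-10 bp) and copy numbers are geometric with
#' mean 6 (minimum 3). Genes and SSR tracts occupy disjoint intervals.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"ma_genome"`:
#'   \item{sequences}{`Biostrings::DNAStringSet`, one entry per chromosome.}
#'   \item{ssr_truth}{Tibble of planted tracts: `chrom`, `start`, `end`
#'     (0-based half-open), `motif` (canonical rotation), `unit_length`,
#'     `copies`.}
#'   \item{genes}{Tibble of gene intervals: `gene_id`, `chrom`, `start`,
#'     `end` (0-based half-open), `strand`.}
#'   \item{config}{The config used.}
#' @export
#' @examples
#' g <- generate_genome(simulation_config(genome_length = 2e4, seed = 42))
#' Biostrings::width(g$sequences)
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .generate_genome_impl(config))
}

.generate_genome_impl <- function(config) {
  L_chr <- rep(floor(config$genome_length / config$n_chromosomes),
               config$n_chromosomes)
  L_chr[config$n_chromosomes] <- L_chr[config$n_chromosomes] +
    config$genome_length - sum(L_chr)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  seqs <- vector("list", config$n_chromosomes)
  ssr_rows <- list()
  gene_rows <- list()
  gene_counter <- 0L

  for (ci in seq_len(config$n_chromosomes)) {
    L <- L_chr[ci]
    base <- .random_bases(L, config$gc_content)

    # gene lengths: ~uniform 300-1500 bp, forced to multiples of 3
    gene_bp_target <- round(config$gene_fraction * L)
    gene_lens <- integer(0)
    bp <- 0
    while (bp < gene_bp_target) {
      len <- 3L * sample(100:500, 1L)
      if (bp + len > gene_bp_target + 750) len <- max(99L, 3L * ((gene_bp_target - bp) %/% 3L))
      if (len < 99L) break
      gene_lens <- c(gene_lens, len)
      bp <- bp + len
    }

    # SSR tract specs: unit from weights, copies = 3 + Geom(mean 3)
    ssr_bp_target <- round(config$ssr_target_fraction * L)
    ssr_units <- integer(0); ssr_copies <- integer(0)
    bp <- 0
    while (bp < ssr_bp_target) {
      u <- sample.int(10L, 1L, prob = config$ssr_unit_weights)
      cp <- 3L + rgeom(1L, 1 / 4)   # mean copies 6, min 3
      if (bp + u * cp > ssr_bp_target + 60) {
        cp <- max(3L, (ssr_bp_target - bp) %/% u)
      }
      if (u * cp < 3L) break
      ssr_units <- c(ssr_units, u); ssr_copies <- c(ssr_copies, cp)
      bp <- bp + u * cp
    }

    lens <- c(gene_lens, ssr_units * ssr_copies)
    kinds <- rep(c("gene", "ssr"), c(length(gene_lens), length(ssr_units)))
    ord <- sample.int(length(lens))
    starts <- .place_intervals(lens[ord], L)
    if (is.null(starts)) {
      abort(paste0(
        "infeasible config on ", chroms[ci],
        ": cannot place ", sum(lens), " bp of genes+SSRs (+gaps) into ",
        L, " bp; reduce gene_fraction or ssr_target_fraction"
      ))
    }
    lens_o <- lens[ord]; kinds_o <- kinds[ord]
    idx_o <- seq_along(lens)[ord]

    n_g <- length(gene_lens); n_s <- length(ssr_units)
    g_start <- integer(n_g); g_strand <- character(n_g); g_len <- integer(n_g)
    s_start <- integer(n_s); s_motif <- character(n_s)
    gi <- 0L; si <- 0L
    for (k in seq_along(starts)) {
      s <- starts[k]; len <- lens_o[k]
      if (kinds_o[k] == "gene") {
        strand <- sample(c("+", "-"), 1L)
        gseq <- .gene_sequence(len, config$gc_content)
        if (strand == "-") {
          gseq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(gseq)
          ))
        }
        base[s:(s + len - 1L)] <- strsplit(gseq, "")[[1]]
        gi <- gi + 1L
        g_start[gi] <- s; g_strand[gi] <- strand; g_len[gi] <- len
      } else {
        j <- idx_o[k] - n_g
        u <- ssr_units[j]; cp <- ssr_copies[j]
        motif <- .ssr_motif(u, config$gc_content)
        base[s:(s + u * cp - 1L)] <- strsplit(strrep(motif, cp), "")[[1]]
        si <- si + 1L
        s_start[si] <- s; s_motif[si] <- motif
      }
    }
    if (n_g > 0) {
      gene_rows[[ci]] <- tibble(
        gene_id = sprintf("gene%04d", gene_counter + seq_len(n_g)),
        chrom = chroms[ci], start = g_start - 1L, end = g_start - 1L + g_len,
        strand = g_strand
      )
      gene_counter <- gene_counter + n_g
    }
    if (n_s > 0) {
      placed_j <- idx_o[kinds_o == "ssr"] - n_g   # spec index per placement
      u_p <- ssr_units[placed_j]; cp_p <- ssr_copies[placed_j]
      ssr_rows[[ci]] <- tibble(
        chrom = chroms[ci], start = s_start - 1L,
        end = s_start - 1L + u_p * cp_p,
        motif = .canonical_rotation(s_motif),
        unit_length = u_p, copies = cp_p
      )
    }
    seqs[[ci]] <- paste(base, collapse = "")
  }

  sequences <- Biostrings::DNAStringSet(setNames(unlist(seqs), chroms))
  ssr_truth <- if (length(ssr_rows)) {
    arrange(list_rbind(ssr_rows), .data$chrom, .data$start)
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           motif = character(), unit_length = integer(), copies = integer())
  }
  genes <- if (length(gene_rows)) {
    arrange(list_rbind(gene_rows), .data$chrom, .data$start)
  } else {
    tibble(gene_id = character(), chrom = character(), start = integer(),
           end = integer(), strand = character())
  }
  structure(
    list(sequences = sequences, ssr_truth = ssr_truth, genes = genes,
         config = config),
    class = "ma_genome"
  )
}

#' @export
print.ma_genome <- function(x, ...) {
  gc <- sum(Biostrings::letterFrequency(x$sequences, "GC")) /
    sum(Biostrings::width(x$sequences))
  cat(sprintf(
    "<ma_genome> %d chromosome(s), %d bp, GC %.3f, %d SSR tracts, %d genes\n",
    length(x$sequences), sum(Biostrings::width(x$sequences)), gc,
    nrow(x$ssr_truth), nrow(x$genes)
  ))
  invisible(x)
}
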