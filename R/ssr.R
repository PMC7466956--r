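# Perfect tandem-repeat (SSR / microsatellite) detection. A tract is a
# maximal run of a repeating unit of length 1-10 bp; it is attributed to
# its smallest repeating period, and overlapping candidate tracts are
# resolved greedily left-to-right (ties: longer tract, then smaller unit).

# minimal period p <= u of s[from..to] (1-based, inclusive); bases as
# a character vector
.minimal_period <- function(chars, from, to, u) {
  for (p in seq_len(u)) {
    if (all(chars[from:(to - p)] == chars[(from + p):to])) return(p)
  }
  u
}

#' Find simple sequence repeats in a reference genome
#'
#' Scans every chromosome for maximal perfect tandem repeats with unit
#' length `1..max_unit`, at least `min_copies` complete copies and tract
#' length at least `min_tract_bp`. Each tract is attributed to its
#' smallest repeating unit (so `ACACAC` is a 2-mer repeat, never a 4-mer
#' one) and reported with the lexicographically smallest rotation of the
#' unit as its canonical motif. Overlapping candidates are resolved
#' greedily left-to-right; among candidates starting at the same position
#' the longer tract wins, then the smaller unit. Runs containing N are
#' never part of a tract. Unit-length-1 loci additionally carry a
#' `homopolymer` flag (A:T homopolymer runs are the classic slippage
#' hotspot in AT-rich genomes).
#'
#' @param reference A [read_reference()] result (or any `DNAStringSet`).
#' @param min_copies Minimum complete copies (default 3).
#' @param min_tract_bp Minimum tract length in bp (default 8).
#' @param max_unit Maximum repeat-unit length (default 10).
#' @return Tibble of SSR loci: `chrom`, `start`, `end` (0-based
#'   half-open), `motif`, `unit_length`, `copies`, `homopolymer`.
#' @export
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "GGCATTTTTTTTTTCAGACACACACACG"))
#' find_ssrs(ref)
find_ssrs <- function(reference, min_copies = 3L, min_tract_bp = 8L,
                      max_unit = 10L) {
  stopifnot(max_unit <= 10L, min_copies >= 2L)
  out <- list()
  for (ch in names(reference)) {
    chars <- strsplit(toupper(as.character(reference[[ch]])), "")[[1]]
    cand <- .ssr_candidates(chars, min_copies, min_tract_bp, max_unit)
    if (nrow(cand) == 0) next
    kept <- .resolve_overlaps(cand)
    kept$chrom <- ch
    out[[ch]] <- kept
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  motif = character(), unit_length = integer(),
                  copies = integer(), homopolymer = logical()))
  }
  res <- list_rbind(out)
  res <- mutate(
    res,
    motif = .canonical_rotation(.data$motif),
    homopolymer = .data$unit_length == 1L
  )
  select(arrange(res, .data$chrom, .data$start),
         "chrom", "start", "end", "motif", "unit_length", "copies",
         "homopolymer")
}

# all maximal period-u runs meeting the thresholds, with minimal-period
# attribution; vectorised per unit length over the match mask
.ssr_candidates <- function(chars, min_copies, min_tract_bp, max_unit) {
  L <- length(chars)
  ok <- chars %in% c("A", "C", "G", "T")
  starts <- integer(0); ends <- integer(0)
  motifs <- character(0); units <- integer(0); copies_v <- integer(0)
  for (u in seq_len(min(max_unit, max(0L, L - 1L)))) {
    if (L < u + 1L) break
    m <- chars[seq_len(L - u)] == chars[(u + 1L):L]
    m <- m & ok[seq_len(L - u)] & ok[(u + 1L):L]
    r <- rle(m)
    ends_rle <- cumsum(r$lengths)
    starts_rle <- ends_rle - r$lengths + 1L
    tract_len <- r$lengths + u
    cps <- tract_len %/% u
    hit <- which(r$values & tract_len >= min_tract_bp & cps >= min_copies)
    for (h in hit) {
      s <- starts_rle[h]           # 1-based start of matching region
      e <- s + tract_len[h] - 1L
      # attribute to smallest period only
      if (u > 1L && .minimal_period(chars, s, e, u) < u) next
      starts <- c(starts, s - 1L); ends <- c(ends, e)   # 0-based half-open
      motifs <- c(motifs, paste(chars[s:(s + u - 1L)], collapse = ""))
      units <- c(units, u); copies_v <- c(copies_v, as.integer(cps[h]))
    }
  }
  tibble(start = starts, end = ends, motif = motifs,
         unit_length = units, copies = copies_v)
}

# greedy left-to-right: sort by (start, longer tract, smaller unit);
# accept a candidate iff it does not overlap an accepted one
.resolve_overlaps <- function(cand) {
  cand <- cand[order(cand$start, -(cand$end - cand$start), cand$unit_length), ]
  keep <- logical(nrow(cand))
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  cand[keep, ]
}

#' Flag mutations by SSR context
#'
#' A substitution is inside an SSR iff its position lies within a locus.
#' An indel is inside iff its affected interval overlaps a locus: for a
#' deletion the anchored base plus the deleted span, for an insertion the
#' anchored base and the base to its right (the inserted sequence sits
#' between them). `flank_bp` widens every locus by that much slack on
#' both sides.
#'
#' @param mutations A mutation tibble.
#' @param ssr_loci A tibble from [find_ssrs()] (or a truth set).
#' @param flank_bp Extra slack around each locus (default 0).
#' @return `mutations` with the `in_ssr` column set.
#' @export
annotate_variants_ssr <- function(mutations, ssr_loci, flank_bp = 0L) {
  .assert_mutations(mutations)
  if (nrow(mutations) == 0) return(mutations)
  span_start <- mutations$pos                      # 1-based inclusive
  span_end <- dplyr::case_when(
    mutations$mclass == "deletion" ~ mutations$pos + mutations$indel_length,
    mutations$mclass == "insertion" ~ mutations$pos + 1L,
    TRUE ~ mutations$pos
  )
  in_ssr <- logical(nrow(mutations))
  for (ch in unique(mutations$chrom)) {
    sel <- mutations$chrom == ch
    loci <- ssr_loci[ssr_loci$chrom == ch, ]
    if (nrow(loci) == 0) next
    q <- IRanges::IRanges(span_start[sel], span_end[sel])
    s <- IRanges::IRanges(loci$start + 1L - flank_bp, loci$end + flank_bp)
    in_ssr[sel] <- IRanges::countOverlaps(q, s) > 0
  }
  mutate(mutations, in_ssr = in_ssr)
}

#' Fraction of callable sites inside SSR loci
#'
#' @param ssr_loci A tibble from [find_ssrs()].
#' @param mask A `"callable_mask"` (or a tibble of intervals).
#' @return `|union(loci) intersect mask| / |mask|`.
#' @export
ssr_genome_fraction <- function(ssr_loci, mask) {
  intervals <- if (inherits(mask, "callable_mask")) mask$intervals else mask
  if (nrow(intervals) == 0) abort("empty callable mask")
  mask_bp <- 0
  hit_bp <- 0
  for (ch in unique(intervals$chrom)) {
    mr <- IRanges::reduce(with(intervals[intervals$chrom == ch, ],
                               IRanges::IRanges(start + 1L, end)))
    mask_bp <- mask_bp + sum(IRanges::width(mr))
    loci <- ssr_loci[ssr_loci$chrom == ch, ]
    if (nrow(loci) == 0) next
    lr <- IRanges::reduce(IRanges::IRanges(loci$start + 1L, loci$end))
    hit_bp <- hit_bp + sum(IRanges::width(IRanges::intersect(mr, lr)))
  }
  if (mask_bp == 0) abort("empty callable mask")
  hit_bp / mask_bp
}

#' Write SSR loci as BED
#'
#' The name field is `motif x copies` (e.g. `Tx12`).
#'
#' @param ssr_loci A tibble from [find_ssrs()].
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_ssr_bed <- function(ssr_loci, path) {
  .write_bed(ssr_loci, path,
             name = function(d) sprintf("%sx%d", d$motif, d$copies))
  invisible(path)
}
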