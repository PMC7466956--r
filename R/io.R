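# Readers for the standard formats an MA analysis consumes: reference
# FASTA, per-line VCF, callable-site BED masks, GFF3 gene models and the
# experiment metadata TSV. Internal coordinates are 0-based half-open for
# intervals and 1-based for point positions (VCF convention).

#' Read and validate a reference genome
#'
#' Sequences are uppercased; only A, C, G, T and N are allowed.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `Biostrings::DNAStringSet` with a `base_stats` attribute: a
#'   tibble of per-chromosome `length`, `n_AT`, `n_GC`, `n_N`.
#' @export
read_reference <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) abort(paste0("empty FASTA: ", fasta_path))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    abort(paste0("duplicate sequence ID in FASTA: ", dup))
  }
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  freq <- Biostrings::alphabetFrequency(seqs)
  legal <- rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
  illegal <- legal < Biostrings::width(seqs)
  if (any(illegal)) {
    abort(paste0("illegal characters (non-ACGTN) in record: ",
                 names(seqs)[illegal][1]))
  }
  stats <- tibble(
    chrom = names(seqs),
    length = Biostrings::width(seqs),
    n_AT = freq[, "A"] + freq[, "T"],
    n_GC = freq[, "G"] + freq[, "C"],
    n_N = freq[, "N"]
  )
  attr(seqs, "base_stats") <- stats
  seqs
}

#' Genome-wide base statistics of a reference
#'
#' @param reference A [read_reference()] result (or any `DNAStringSet`).
#' @return One-row tibble: `length`, `n_AT`, `n_GC`, `n_N`, `gc_fraction`
#'   (of non-N sites).
#' @export
reference_base_stats <- function(reference) {
  freq <- Biostrings::alphabetFrequency(reference, baseOnly = TRUE)
  n_AT <- sum(freq[, c("A", "T")])
  n_GC <- sum(freq[, c("C", "G")])
  len <- sum(Biostrings::width(reference))
  tibble(
    length = len, n_AT = n_AT, n_GC = n_GC, n_N = len - n_AT - n_GC,
    gc_fraction = n_GC / (n_AT + n_GC)
  )
}

# mask tibble (chrom/start/end, 0-based half-open) -> IRangesList by chrom
.mask_to_ranges <- function(mask) {
  sp <- split(mask, mask$chrom)
  lapply(sp, function(d) {
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
  })
}

#' Read a callable-site mask (BED) and count callable bases
#'
#' Overlapping or adjacent intervals are merged. `n` counts covered non-N
#' reference positions; `n_AT` and `n_GC` split them by reference base.
#'
#' @param bed_path Path to a BED file (0-based half-open).
#' @param reference A [read_reference()] result.
#' @return A list of class `"callable_mask"`: `intervals` (tibble `chrom`,
#'   `start`, `end`, merged), `n`, `n_AT`, `n_GC`.
#' @export
read_callable_mask <- function(bed_path, reference) {
  bed <- readr::read_tsv(
    bed_path,
    col_names = c("chrom", "start", "end"),
    col_types = readr::cols_only(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer()
    ),
    progress = FALSE
  )
  if (nrow(bed) == 0) {
    return(structure(
      list(intervals = tibble(chrom = character(), start = integer(),
                              end = integer()), n = 0L, n_AT = 0L, n_GC = 0L),
      class = "callable_mask"
    ))
  }
  if (any(bed$end <= bed$start)) {
    abort("BED interval with end <= start")
  }
  unknown <- setdiff(unique(bed$chrom), names(reference))
  if (length(unknown) > 0) {
    abort(paste0("BED chromosome not in reference: ", unknown[1]))
  }
  lens <- setNames(Biostrings::width(reference), names(reference))
  if (any(bed$end > lens[bed$chrom])) {
    abort("BED interval beyond chromosome end")
  }
  mask_counts(bed, reference)
}

#' Count callable sites under a mask
#'
#' @param intervals Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param reference A [read_reference()] result.
#' @return A `"callable_mask"` object (see [read_callable_mask()]).
#' @export
mask_counts <- function(intervals, reference) {
  rngl <- .mask_to_ranges(intervals)
  n <- 0L; n_AT <- 0L; n_GC <- 0L
  merged <- list()
  for (ch in names(rngl)) {
    r <- rngl[[ch]]
    v <- Biostrings::Views(reference[[ch]], start = IRanges::start(r),
                           end = IRanges::end(r))
    f <- Biostrings::letterFrequency(v, c("A", "T", "G", "C"))
    n_AT <- n_AT + sum(f[, c("A", "T")])
    n_GC <- n_GC + sum(f[, c("G", "C")])
    merged[[ch]] <- tibble(chrom = ch, start = IRanges::start(r) - 1L,
                           end = IRanges::end(r))
  }
  n <- n_AT + n_GC   # N bases excluded by construction
  structure(
    list(intervals = arrange(list_rbind(merged), .data$chrom, .data$start),
         n = as.integer(n), n_AT = as.integer(n_AT), n_GC = as.integer(n_GC)),
    class = "callable_mask"
  )
}

#' @export
print.callable_mask <- function(x, ...) {
  cat(sprintf("<callable_mask> %d interval(s), n = %d (A/T %d, G/C %d)\n",
              nrow(x$intervals), x$n, x$n_AT, x$n_GC))
  invisible(x)
}

# is each (chrom, pos [1-based]) inside the mask?
.in_mask <- function(chrom, pos, mask) {
  rngl <- .mask_to_ranges(mask$intervals)
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (!ch %in% names(rngl)) next
    hits <- IRanges::countOverlaps(IRanges::IRanges(pos[sel], width = 1L),
                                   rngl[[ch]])
    out[sel] <- hits > 0
  }
  out
}

#' Read single-sample variant calls for one MA line
#'
#' Classifies records as substitutions or 1-30 bp insertions/deletions
#' (VCF left-anchored, one base of context). Indels longer than 30 bp and
#' variants outside the line's callable mask are dropped with a message;
#' REF alleles are checked against the reference and a mismatch is an
#' error. Multi-allelic records are rejected unless
#' `split_multiallelic = TRUE`. Records where REF and ALT are both longer
#' than one base (complex substitutions) are classified by net length
#' change and flagged in the `complex` column.
#'
#' @param vcf_path Path to a VCF file.
#' @param line One row of a lines tibble (needs `line_id`); optional.
#' @param reference A [read_reference()] result.
#' @param mask Optional `"callable_mask"`; variants outside it are dropped.
#' @param split_multiallelic Split `ALT=a,b` records instead of erroring.
#' @return A mutation tibble: `line_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `mclass`, `indel_length`, `complex`, plus `in_ssr`/`region`/`effect`
#'   columns initialised to `NA` for downstream annotation.
#' @export
read_line_variants <- function(vcf_path, line = NULL, reference,
                               mask = NULL, split_multiallelic = FALSE) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  line_id <- if (!is.null(line)) line$line_id[1] else NA_character_
  if (nrow(fix) == 0) {
    return(mutate(.empty_mutations(), complex = logical()))
  }
  fix$POS <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(fix$POS) || any(fix$POS < 1)) abort("malformed POS in VCF")

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (!split_multiallelic) {
      abort(paste0("multi-allelic record at ", fix$CHROM[multi][1], ":",
                   fix$POS[multi][1],
                   " (haploid single-isolate calls expected; ",
                   "use split_multiallelic = TRUE to split)"))
    }
    split_rows <- map(which(multi), function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      out <- fix[rep(i, length(alts)), ]
      out$ALT <- alts
      out
    })
    fix <- bind_rows(fix[!multi, ], bind_rows(split_rows))
  }

  unknown <- setdiff(unique(fix$CHROM), names(reference))
  if (length(unknown) > 0) {
    abort(paste0("VCF chromosome not in reference: ", unknown[1]))
  }
  lens <- setNames(Biostrings::width(reference), names(reference))
  if (any(fix$POS + nchar(fix$REF) - 1L > lens[fix$CHROM])) {
    abort("VCF record extends beyond chromosome end")
  }

  # REF must match the reference sequence
  obs <- vapply(seq_len(nrow(fix)), function(i) {
    as.character(Biostrings::subseq(reference[[fix$CHROM[i]]],
                                    start = fix$POS[i],
                                    width = nchar(fix$REF[i])))
  }, character(1))
  bad <- toupper(fix$REF) != obs
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("REF mismatch at ", fix$CHROM[i], ":", fix$POS[i],
                 " (VCF ", fix$REF[i], ", reference ", obs[i], ")"))
  }

  lr <- nchar(fix$REF); la <- nchar(fix$ALT)
  net <- la - lr
  mclass <- dplyr::case_when(
    lr == 1 & la == 1 ~ "substitution",
    net > 0 ~ "insertion",
    net < 0 ~ "deletion",
    TRUE ~ "complex"
  )
  if (any(mclass == "complex")) {
    # same-length multi-base record: not representable as net change
    abort(paste0("unclassifiable VCF record (REF and ALT same length > 1) at ",
                 fix$CHROM[mclass == "complex"][1]))
  }
  complex_flag <- lr > 1 & la > 1

  out <- tibble(
    line_id = line_id, chrom = fix$CHROM, pos = fix$POS,
    ref = toupper(fix$REF), alt = toupper(fix$ALT),
    mclass = mclass, indel_length = abs(net),
    complex = complex_flag,
    in_ssr = NA, region = NA_character_, effect = NA_character_
  )

  too_long <- out$indel_length > 30L
  if (any(too_long)) {
    inform(sprintf("dropped %d indel(s) longer than 30 bp", sum(too_long)))
    out <- out[!too_long, ]
  }
  if (!is.null(mask)) {
    inside <- .in_mask(out$chrom, out$pos, mask)
    if (any(!inside)) {
      inform(sprintf("dropped %d variant(s) outside the callable mask",
                     sum(!inside)))
      out <- out[inside, ]
    }
  }
  mutate(out, indel_length = as.integer(.data$indel_length))
}

#' Read CDS gene models from GFF3
#'
#' Genes whose total CDS length is not divisible by 3 are excluded with a
#' warning (their count is recorded in the `n_excluded` attribute).
#'
#' @param gff_path Path to a GFF3 file with CDS features.
#' @return Tibble of CDS segments: `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `segment` (order along the transcript,
#'   5' to 3').
#' @export
read_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) abort(paste0("no CDS features in ", gff_path))
  parent <- as.character(S4Vectors::mcols(cds)$Parent)
  if (all(is.na(parent)) || length(parent) == 0) {
    parent <- as.character(S4Vectors::mcols(cds)$ID)
  }
  df <- tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds))
  )
  df <- arrange(df, .data$gene_id, .data$start)
  tot <- summarise(group_by(df, .data$gene_id),
                   bp = sum(.data$end - .data$start), .groups = "drop")
  bad <- tot$gene_id[tot$bp %% 3L != 0L]
  if (length(bad) > 0) {
    warn(sprintf("%d gene(s) with CDS length not divisible by 3 excluded from effect calling",
                 length(bad)))
    df <- filter(df, !.data$gene_id %in% bad)
  }
  df <- df %>%
    group_by(.data$gene_id) %>%
    mutate(segment = if (dplyr::first(.data$strand) == "-") {
      rev(row_number())
    } else {
      row_number()
    }) %>%
    ungroup()
  attr(df, "n_excluded") <- length(bad)
  df
}

#' Read MA-experiment metadata
#'
#' Expects a TSV with columns `line_id`, `lab`, `generations`, `vcf_path`,
#' `mask_path` (paths relative to the TSV's directory).
#'
#' @param tsv_path Path to the metadata table.
#' @return Tibble with absolute `vcf_path`/`mask_path`.
#' @export
read_ma_metadata <- function(tsv_path) {
  meta <- readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
  need <- c("line_id", "lab", "generations", "vcf_path", "mask_path")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(meta$generations <= 0)) abort("generations must be > 0")
  base <- dirname(tsv_path)
  mutate(
    meta,
    vcf_path = if_else(file.exists(.data$vcf_path), .data$vcf_path,
                       file.path(base, .data$vcf_path)),
    mask_path = if_else(file.exists(.data$mask_path), .data$mask_path,
                        file.path(base, .data$mask_path))
  )
}
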