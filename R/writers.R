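# Plain-text export of a simulated experiment: FASTA (60-col), per-line
# VCF v4.2, BED (0-based half-open) for SSR truth and callable masks, GFF3
# gene models, a truth TSV and a YAML config echo. Output is a pure
# function of (genome, truth), so identical seeds give identical bytes.

.write_vcf_body <- function(mutations, contigs, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutacc-simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), unname(contigs)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(mutations) > 0) {
    m <- arrange(mutations, .data$chrom, .data$pos)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    m$chrom, m$pos, m$ref, m$alt)
  }
  writeLines(c(hdr, body), path)
}

.write_bed <- function(df, path, name = NULL) {
  if (nrow(df) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- arrange(df, .data$chrom, .data$start)
  lines <- if (is.null(name)) {
    sprintf("%s\t%d\t%d", df$chrom, df$start, df$end)
  } else {
    sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, name(df))
  }
  writeLines(lines, path)
}

#' Write a simulated MA experiment to disk
#'
#' Writes `reference.fasta`, per-line `*.vcf` and callable-mask `*.bed`
#' files, `ssr_truth.bed` (name field `motif x copies`), `genes.gff3`,
#' `truth_mutations.tsv`, `lines.tsv` (experiment metadata: line_id, lab,
#' generations, vcf_path, mask_path) and `config.yaml` under `dir`.
#'
#' @param genome A [generate_genome()] result.
#' @param truth A [simulate_ma_lines()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_ma_experiment <- function(genome, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list()

  p$fasta <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(genome$sequences, p$fasta, width = 60L)

  contigs <- setNames(Biostrings::width(genome$sequences),
                      names(genome$sequences))

  p$ssr_truth <- file.path(dir, "ssr_truth.bed")
  .write_bed(genome$ssr_truth, p$ssr_truth,
             name = function(d) sprintf("%sx%d", d$motif, d$copies))

  p$gff <- file.path(dir, "genes.gff3")
  g <- arrange(genome$genes, .data$chrom, .data$start)
  gff <- c(
    "##gff-version 3",
    unlist(map(seq_len(nrow(g)), function(i) {
      r <- g[i, ]
      c(
        sprintf("%s\tmutacc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                r$chrom, r$start + 1L, r$end, r$strand, r$gene_id),
        sprintf("%s\tmutacc\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                r$chrom, r$start + 1L, r$end, r$strand, r$gene_id, r$gene_id)
      )
    }))
  )
  writeLines(gff, p$gff)

  vcf_paths <- character(0)
  mask_paths <- character(0)
  for (lid in truth$lines$line_id) {
    vp <- file.path(dir, paste0(lid, ".vcf"))
    .write_vcf_body(filter(truth$mutations, .data$line_id == lid), contigs, vp)
    mp <- file.path(dir, paste0(lid, ".callable.bed"))
    .write_bed(select(filter(truth$masks, .data$line_id == lid),
                      "chrom", "start", "end"), mp)
    vcf_paths <- c(vcf_paths, vp)
    mask_paths <- c(mask_paths, mp)
  }
  p$vcf <- vcf_paths
  p$masks <- mask_paths

  p$metadata <- file.path(dir, "lines.tsv")
  meta <- mutate(
    select(truth$lines, "line_id", "lab", "generations"),
    vcf_path = basename(vcf_paths), mask_path = basename(mask_paths)
  )
  readr::write_tsv(meta, p$metadata)

  p$truth <- file.path(dir, "truth_mutations.tsv")
  readr::write_tsv(truth$mutations, p$truth)

  p$config <- file.path(dir, "config.yaml")
  cfg <- unclass(truth$config)
  yaml::write_yaml(cfg, p$config)

  invisible(p)
}
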