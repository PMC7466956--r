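# Forward simulation of mutation accumulation: per line, substitution and
# indel events arrive Poisson over callable site-generations, placed
# uniformly; indels inside SSR tracts are slippage events (+/- one repeat
# unit) at an elevated rate; a configurable fraction of substitution events
# arrive as multinucleotide pairs within +/- 50 bp.

MNM_PAIR_WINDOW <- 50L

# per-line callable mask: random subset of 500 bp tiles per chromosome,
# hitting callable_fraction as closely as tile granularity allows
.simulate_mask <- function(chrom_lengths, callable_fraction, tile = 500L) {
  rows <- imap(chrom_lengths, function(L, chrom) {
    n_tiles <- ceiling(L / tile)
    keep <- sort(sample.int(n_tiles, max(1L, round(callable_fraction * n_tiles))))
    start <- (keep - 1L) * tile
    end <- pmin(keep * tile, L)
    # merge adjacent kept tiles
    grp <- cumsum(c(1L, diff(keep) != 1L))
    tibble(
      chrom = chrom,
      start = as.integer(tapply(start, grp, min)),
      end = as.integer(tapply(end, grp, max))
    )
  })
  list_rbind(rows)
}

# flatten a mask tibble into a vector of 1-based callable positions,
# offset per chromosome into a single global coordinate for fast sampling
.mask_positions <- function(mask, chrom_lengths) {
  offs <- cumsum(c(0, unname(chrom_lengths)))
  names(offs) <- c(names(chrom_lengths), ".end")
  pos <- map2(mask$start, mask$end, function(s, e) seq.int(s + 1L, e))
  glob <- unlist(map2(pos, mask$chrom, function(p, ch) p + offs[[ch]]))
  list(global = glob, offsets = offs[names(chrom_lengths)])
}

.global_to_local <- function(g, offsets) {
  chrom_idx <- findInterval(g, unname(offsets) + 1L)
  tibble(chrom = names(offsets)[chrom_idx],
         pos = as.integer(g - unname(offsets)[chrom_idx]))
}

#' Simulate mutation accumulation across MA lines
#'
#' Each line accrues a Poisson number of substitution events with mean
#' `mu_bs * callable_sites * generations / (1 + mnm_fraction)`, placed
#' uniformly over its callable sites; because a fraction of events spawn a
#' second paired substitution (below), the expected substitution count per
#' line is `mu_bs * callable_sites * generations`, so the configured rate
#' is the per-site rate of called substitutions, matching the raw-count
#' estimator. Each event first draws its six-class identity from the
#' configured spectrum weights and then lands on a uniformly chosen
#' callable site of the matching base pair, so realised class frequencies
#' follow the weights and per-site rates at A:T versus G:C sites differ
#' exactly as the weights imply (a G/C->A/T-biased spectrum makes G/C
#' sites individually hotter in an AT-rich genome). With
#' probability `mnm_fraction` an event is a multinucleotide pair: a partner
#' substitution is placed uniformly within +/- 50 bp (excluding the focal
#' site) on the same line. Indel events arrive at `mu_indel` per callable
#' site-generation outside SSR tracts and `mu_indel * ssr_slippage_multiplier`
#' inside; slippage indels add or remove one repeat unit of the containing
#' tract, other indels draw lengths 1-30 bp from the configured
#' distribution, with `deletion_fraction` of events deleting. Later events
#' replace earlier ones at an already-mutated site (with a warning); this
#' resolution is deterministic.
#'
#' @param genome An [generate_genome()] result.
#' @param config The same [simulation_config()].
#' @return A list of class `"ma_truth"`:
#'   \item{lines}{Tibble: `line_id`, `lab`, `generations`, `callable_sites`,
#'     `callable_AT_sites`, `callable_GC_sites`.}
#'   \item{masks}{Tibble of callable intervals per line (0-based half-open).}
#'   \item{mutations}{Truth mutation tibble with `event_id` (an MNM pair
#'     shares one id), `mclass`, `indel_length`, `in_ssr`, `region` and
#'     `effect` truth labels.}
#'   \item{per_line_event_counts}{Tibble `line_id`, `n_events` (distinct
#'     mutational events; an MNM pair counts once).}
#' @export
simulate_ma_lines <- function(genome, config) {
  stopifnot(inherits(genome, "ma_genome"), inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 1L, .simulate_lines_impl(genome, config))
}

.simulate_lines_impl <- function(genome, config) {
  chrom_lengths <- setNames(Biostrings::width(genome$sequences),
                            names(genome$sequences))
  chrom_strings <- as.character(genome$sequences)
  seq_chars <- setNames(
    lapply(chrom_strings, function(s) strsplit(s, "")[[1]]),
    names(genome$sequences)
  )
  glob_chars <- unlist(seq_chars, use.names = FALSE)

  # SSR / gene occupancy as global vectors over concatenated chromosomes
  offs <- cumsum(c(0, unname(chrom_lengths)))[seq_along(chrom_lengths)]
  names(offs) <- names(chrom_lengths)
  total_len <- sum(chrom_lengths)
  ssr_id_glob <- integer(total_len)
  if (nrow(genome$ssr_truth) > 0) {
    for (i in seq_len(nrow(genome$ssr_truth))) {
      r <- genome$ssr_truth[i, ]
      ssr_id_glob[(offs[[r$chrom]] + r$start + 1L):(offs[[r$chrom]] + r$end)] <- i
    }
  }
  in_ssr_glob <- ssr_id_glob > 0L
  in_gene_glob <- logical(total_len)
  if (nrow(genome$genes) > 0) {
    for (i in seq_len(nrow(genome$genes))) {
      r <- genome$genes[i, ]
      in_gene_glob[(offs[[r$chrom]] + r$start + 1L):(offs[[r$chrom]] + r$end)] <- TRUE
    }
  }

  line_ids <- sprintf("L%02d", seq_len(config$n_lines))
  labs <- rep(c("L", "QS"), length.out = config$n_lines)
  w_spec <- config$spectrum_weights
  is_at_glob <- glob_chars == "A" | glob_chars == "T"

  masks <- list(); line_rows <- list(); mut_rows <- list()
  event_counter <- 0L

  for (li in seq_len(config$n_lines)) {
    mask <- .simulate_mask(chrom_lengths, config$callable_fraction)
    mp <- .mask_positions(mask, chrom_lengths)
    callable <- sort(mp$global)
    n_call <- length(callable)
    if (n_call == 0) abort("zero callable sites for a line")
    Tgen <- config$generations_per_line[li]

    n_AT <- sum(is_at_glob[callable])
    n_GC <- n_call - n_AT            # simulated genomes are N-free

    exp_bs <- config$mu_bs * n_call * Tgen
    callable_ssr <- in_ssr_glob[callable]
    n_call_ssr <- sum(callable_ssr)
    exp_indel <- config$mu_indel * Tgen *
      (n_call - n_call_ssr + config$ssr_slippage_multiplier * n_call_ssr)
    if (exp_bs > 0.1 * n_call || exp_indel > 0.1 * n_call) {
      abort("mutation rates imply saturation (> 0.1 expected events per callable site)")
    }

    line_rows[[li]] <- tibble(
      line_id = line_ids[li], lab = labs[li], generations = Tgen,
      callable_sites = n_call, callable_AT_sites = n_AT,
      callable_GC_sites = n_GC, callable_SSR_sites = n_call_ssr
    )
    masks[[li]] <- mutate(mask, line_id = line_ids[li], .before = 1)

    ## substitutions -----------------------------------------------------
    # event intensity is thinned by (1 + mnm_fraction) so that the
    # expected substitution COUNT (events + MNM partners) is mu_bs * n * T
    n_bs_events <- rpois(1L, exp_bs / (1 + config$mnm_fraction))
    sub_tbl <- NULL
    if (n_bs_events > 0) {
      # class first (marginal = spectrum_weights), then a uniform site of
      # the matching base pair, so per-site rates differ between A:T and
      # G:C sites exactly as the configured spectrum implies
      callable_at <- callable[is_at_glob[callable]]
      callable_gc <- callable[!is_at_glob[callable]]
      if (length(callable_at) == 0) {
        w_ev <- c(0, 0, 0, w_spec[4:6])
      } else if (length(callable_gc) == 0) {
        w_ev <- c(w_spec[1:3], 0, 0, 0)
      } else {
        w_ev <- w_spec
      }
      focal_cls <- sample.int(6L, n_bs_events, replace = TRUE, prob = w_ev)
      focal <- integer(n_bs_events)
      at_ev <- focal_cls <= 3L
      if (any(at_ev)) {
        focal[at_ev] <- callable_at[sample.int(length(callable_at),
                                               sum(at_ev), replace = TRUE)]
      }
      if (any(!at_ev)) {
        focal[!at_ev] <- callable_gc[sample.int(length(callable_gc),
                                                sum(!at_ev), replace = TRUE)]
      }
      paired <- runif(n_bs_events) < config$mnm_fraction
      event_ids <- event_counter + seq_len(n_bs_events)
      event_counter <- event_counter + n_bs_events

      partner_g <- integer(0); partner_ev <- integer(0)
      for (k in which(paired)) {
        g <- focal[k]
        chrom_idx <- findInterval(g, unname(offs) + 1L)
        lo <- max(offs[[chrom_idx]] + 1L, g - MNM_PAIR_WINDOW)
        hi <- min(offs[[chrom_idx]] + chrom_lengths[[chrom_idx]],
                  g + MNM_PAIR_WINDOW)
        i1 <- findInterval(lo - 1L, callable) + 1L
        i2 <- findInterval(hi, callable)
        if (i2 < i1) next
        cand <- callable[i1:i2]
        cand <- cand[cand != g]
        if (length(cand) == 0) next
        partner_g <- c(partner_g, cand[sample.int(length(cand), 1L)])
        partner_ev <- c(partner_ev, event_ids[k])
      }

      all_g <- c(focal, partner_g)
      all_ev <- c(event_ids, partner_ev)
      all_mnm <- c(paired, rep(TRUE, length(partner_g)))
      ref <- glob_chars[all_g]
      # focal classes were drawn marginally; MNM partners sit wherever the
      # window allows, so their class is conditional on the local ref base
      cls_idx <- c(focal_cls, integer(length(partner_g)))
      if (length(partner_g) > 0) {
        p_idx <- n_bs_events + seq_along(partner_g)
        p_at <- is_at_glob[partner_g]
        if (any(p_at)) {
          cls_idx[p_idx[p_at]] <- sample.int(3L, sum(p_at), replace = TRUE,
                                             prob = w_spec[1:3])
        }
        if (any(!p_at)) {
          cls_idx[p_idx[!p_at]] <- 3L + sample.int(3L, sum(!p_at),
                                                   replace = TRUE,
                                                   prob = w_spec[4:6])
        }
      }
      cls <- SPECTRUM_CLASSES[cls_idx]
      chrom_idx <- findInterval(all_g, unname(offs) + 1L)
      sub_tbl <- tibble(
        line_id = line_ids[li],
        chrom = names(offs)[chrom_idx],
        pos = as.integer(all_g - unname(offs)[chrom_idx]),
        ref = ref, alt = .class_alt(ref, cls),
        mclass = "substitution", indel_length = 0L,
        in_ssr = in_ssr_glob[all_g],
        region = if_else(in_gene_glob[all_g], "coding", "noncoding"),
        effect = NA_character_, event_id = all_ev, mnm = all_mnm
      )
    }

    ## indels -------------------------------------------------------------
    n_indel <- rpois(1L, exp_indel)
    ind_tbl <- NULL
    if (n_indel > 0) {
      w <- ifelse(callable_ssr, config$ssr_slippage_multiplier, 1)
      g <- callable[sample.int(n_call, n_indel, replace = TRUE,
                               prob = w / sum(w))]
      ev <- event_counter + seq_len(n_indel)
      event_counter <- event_counter + n_indel
      chrom_idx <- findInterval(g, unname(offs) + 1L)
      chrom <- names(offs)[chrom_idx]
      L <- unname(chrom_lengths)[chrom_idx]
      pos <- as.integer(g - unname(offs)[chrom_idx])
      sid <- ssr_id_glob[g]
      len <- integer(n_indel)
      len[sid > 0L] <- genome$ssr_truth$unit_length[sid[sid > 0L]]
      n_bg <- sum(sid == 0L)
      if (n_bg > 0) {
        len[sid == 0L] <- sample.int(30L, n_bg, replace = TRUE,
                                     prob = config$indel_length_distribution)
      }
      is_del <- runif(n_indel) < config$deletion_fraction
      is_del[pos >= L] <- FALSE                 # nothing right of the anchor
      len <- if_else(is_del, pmin(len, L - pos), len)
      anchor <- glob_chars[g]

      ref <- anchor
      alt <- anchor
      if (any(is_del)) {
        ref[is_del] <- paste0(
          anchor[is_del],
          substring(chrom_strings[chrom[is_del]],
                    pos[is_del] + 1L, pos[is_del] + len[is_del])
        )
      }
      ins_i <- which(!is_del)
      if (length(ins_i) > 0) {
        ins_seq <- character(length(ins_i))
        from_ssr <- sid[ins_i] > 0L
        ins_seq[from_ssr] <- genome$ssr_truth$motif[sid[ins_i][from_ssr]]
        for (j in which(!from_ssr)) {
          ins_seq[j] <- paste(.random_bases(len[ins_i[j]], config$gc_content),
                              collapse = "")
        }
        len[ins_i] <- nchar(ins_seq)
        alt[ins_i] <- paste0(anchor[ins_i], ins_seq)
      }
      ind_tbl <- tibble(
        line_id = line_ids[li], chrom = chrom, pos = pos,
        ref = ref, alt = alt,
        mclass = if_else(is_del, "deletion", "insertion"),
        indel_length = as.integer(len),
        in_ssr = sid > 0L,
        region = if_else(in_gene_glob[g], "coding", "noncoding"),
        effect = NA_character_, event_id = ev, mnm = FALSE
      )
    }
    mut_rows[[li]] <- bind_rows(sub_tbl, ind_tbl)
  }

  mutations <- list_rbind(mut_rows)
  if (nrow(mutations) > 0) {
    mutations <- arrange(mutations, .data$line_id, .data$chrom, .data$pos,
                         .data$event_id)
    # overlap resolution: at one (line, chrom, pos) the later event wins
    dup <- duplicated(mutations[, c("line_id", "chrom", "pos")], fromLast = TRUE)
    if (any(dup)) {
      warn(sprintf("%d colliding event(s) at already-mutated sites replaced by the later event", sum(dup)))
      mutations <- mutations[!dup, ]
    }
  } else {
    mutations <- mutate(.empty_mutations(), event_id = integer(), mnm = logical())
  }

  lines <- list_rbind(line_rows)
  counts <- lines %>%
    select("line_id") %>%
    left_join(
      summarise(group_by(mutations, .data$line_id),
                n_events = dplyr::n_distinct(.data$event_id), .groups = "drop"),
      by = "line_id"
    ) %>%
    mutate(n_events = dplyr::coalesce(.data$n_events, 0L))

  structure(
    list(lines = lines, masks = list_rbind(masks), mutations = mutations,
         per_line_event_counts = counts, config = config),
    class = "ma_truth"
  )
}
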