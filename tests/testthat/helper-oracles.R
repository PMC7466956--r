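# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive (explicit loops, direct summation) so they share no
# code path with the implementation they check.

# ---- brute-force SSR oracle ------------------------------------------------
# Enumerate every maximal perfect tandem tract by explicit extension from
# every (start, unit) pair, apply the same thresholds and the same
# left-to-right greedy resolution, independently re-implemented.
brute_force_ssrs <- function(seq_string, min_copies = 3L, min_tract_bp = 8L,
                             max_unit = 10L) {
  chars <- strsplit(toupper(seq_string), "")[[1]]
  L <- length(chars)
  acgt <- chars %in% c("A", "C", "G", "T")
  cand <- list()
  for (i in seq_len(L)) {
    for (u in seq_len(max_unit)) {
      if (i + u - 1L > L) break
      # left-maximality: extending one base left must break the period
      if (i > 1L && acgt[i - 1L] && acgt[i - 1L + u] &&
          chars[i - 1L] == chars[i - 1L + u]) next
      # all unit bases must be ACGT
      if (!all(acgt[i:(i + u - 1L)])) next
      # extend right while the period-u property holds
      j <- i + u
      while (j <= L && acgt[j] && chars[j] == chars[j - u]) j <- j + 1L
      tract_len <- j - i
      copies <- tract_len %/% u
      if (tract_len < min_tract_bp || copies < min_copies) next
      # smallest-period attribution: any smaller period over the tract wins
      if (u > 1L) {
        smaller <- FALSE
        for (p in seq_len(u - 1L)) {
          if (all(chars[i:(j - 1L - p)] == chars[(i + p):(j - 1L)])) {
            smaller <- TRUE; break
          }
        }
        if (smaller) next
      }
      cand[[length(cand) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + tract_len,
        motif = paste(chars[i:(i + u - 1L)], collapse = ""),
        unit_length = u, copies = copies
      )
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_length = integer(),
                      copies = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- unique(cand)
  # greedy left-to-right, ties: longer tract, then smaller unit
  cand <- cand[order(cand$start, -(cand$end - cand$start), cand$unit_length), ]
  keep <- rep(FALSE, nrow(cand))
  last_end <- -1L
  for (r in seq_len(nrow(cand))) {
    if (cand$start[r] >= last_end) {
      keep[r] <- TRUE
      last_end <- cand$end[r]
    }
  }
  cand[keep, , drop = FALSE]
}

# lexicographically smallest rotation (oracle-side copy)
rotate_min <- function(m) {
  n <- nchar(m)
  if (n == 1) return(m)
  min(vapply(seq_len(n), function(i) {
    paste0(substr(m, i, n), substr(m, 1, i - 1))
  }, character(1)))
}

random_dna <- function(n, gc = 0.3) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# ---- MNM oracles -----------------------------------------------------------
# transitive closure over the "within window" relation, by explicit
# all-pairs chaining (checks the single-linkage implementation)
brute_force_clusters <- function(pos, window = 50L) {
  n <- length(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(pos[i] - pos[j]) <= window && grp[i] != grp[j]) {
          grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  grp
}

# Monte-Carlo placement oracle for the chance-MNM probability
mc_mnm_probability <- function(m, n, window = 50, trials = 1e5) {
  if (m == 2) {
    hit <- abs(runif(trials, 0, n) - runif(trials, 0, n)) <= window
    return(mean(hit))
  }
  hits <- vapply(seq_len(trials), function(i) {
    p <- sort(runif(m, 0, n))
    any(diff(p) <= window)
  }, logical(1))
  mean(hits)
}

# ---- misc ------------------------------------------------------------------
# exact upper-tail binomial by direct pmf summation
binom_upper_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(x) {
    choose(n, x) * p^x * (1 - p)^(n - x)
  }, numeric(1)))
}

# enumeration oracle for neutral N/S opportunities: every sense codon of
# the standard code, all 9 changes, transition weight kappa, usage weights
enumerate_ns <- function(kappa = 1, usage = NULL) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  if (is.null(usage)) usage <- stats::setNames(rep(1, length(sense)), sense)
  ts_pair <- c(A = "G", G = "A", C = "T", T = "C")
  N <- 0; S <- 0
  for (codon in sense) {
    u <- usage[[codon]]
    for (p in 1:3) {
      b <- substr(codon, p, p)
      for (a in setdiff(c("A", "C", "G", "T"), b)) {
        w <- if (ts_pair[[b]] == a) kappa else 1
        mut <- codon
        substr(mut, p, p) <- a
        if (code[[mut]] == code[[codon]]) S <- S + u * w else N <- N + u * w
      }
    }
  }
  c(N = N, S = S)
}

# ---- shared simulated experiment ------------------------------------------
# one moderately sized experiment, generated once per test run
.fixture_env <- new.env(parent = emptyenv())

small_experiment <- function() {
  if (!is.null(.fixture_env$exp)) return(.fixture_env$exp)
  cfg <- simulation_config(
    genome_length = 1e5, n_chromosomes = 2, n_lines = 10,
    generations_per_line = 20, mu_bs = 2e-5, mu_indel = 2e-5,
    mnm_fraction = 0.1, seed = 101
  )
  genome <- generate_genome(cfg)
  truth <- suppressWarnings(simulate_ma_lines(genome, cfg))
  dir <- file.path(tempdir(), "mutacc-fixture")
  paths <- write_ma_experiment(genome, truth, dir)
  .fixture_env$exp <- list(cfg = cfg, genome = genome, truth = truth,
                           dir = dir, paths = paths)
  .fixture_env$exp
}
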