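# Multinucleotide mutation (MNM) handling: single-linkage chaining of
# mutations within a 50 bp window on one line, collapse of clusters into
# single events, a birthday-type closed form for the chance probability of
# clustering, and a binned Poisson goodness-of-fit test on per-line event
# counts.

#' Detect multinucleotide mutation clusters
#'
#' Per line and chromosome, mutations are sorted by position and chained
#' whenever successive gaps are at most `window` bp (single linkage, so a
#' cluster's total span may exceed the window). Indels participate via
#' their anchored position. With `strict = TRUE` a chain is additionally
#' broken so that every pairwise distance within a cluster is at most
#' `window`.
#'
#' @param mutations A mutation tibble.
#' @param window Clustering window in bp (default 50).
#' @param strict Require all pairwise distances <= window (default FALSE).
#' @return A list of class `"mnm_result"`:
#'   \item{members}{`mutations` with `cluster_id` (NA for singletons).}
#'   \item{clusters}{Tibble: `cluster_id`, `line_id`, `chrom`, `size`,
#'     `span_bp`, `start`, `end`.}
#'   \item{events}{Tibble per line: `n_raw` mutations, `n_clusters`,
#'     `n_events` corrected count (singletons + clusters).}
#' @export
#' @examples
#' m <- tibble::tibble(
#'   line_id = "L01", chrom = "chr1", pos = c(100L, 120L, 400L),
#'   ref = "A", alt = "T", mclass = "substitution", indel_length = 0L
#' )
#' detect_mnms(m)$events
detect_mnms <- function(mutations, window = 50L, strict = FALSE) {
  .assert_mutations(mutations)
  if (nrow(mutations) == 0) {
    return(structure(
      list(
        members = mutate(mutations, cluster_id = character(0)),
        clusters = tibble(cluster_id = character(), line_id = character(),
                          chrom = character(), size = integer(),
                          span_bp = integer(), start = integer(),
                          end = integer()),
        events = tibble(line_id = character(), n_raw = integer(),
                        n_clusters = integer(), n_events = integer())
      ),
      class = "mnm_result"
    ))
  }
  m <- arrange(mutations, .data$line_id, .data$chrom, .data$pos)
  m <- m %>%
    group_by(.data$line_id, .data$chrom) %>%
    mutate(.chain = cumsum(c(1L, as.integer(diff(.data$pos) > window)))) %>%
    ungroup()
  if (strict) {
    # split chains further so max span within a group stays <= window
    m <- m %>%
      group_by(.data$line_id, .data$chrom, .data$.chain) %>%
      mutate(.chain2 = .strict_split(.data$pos, window)) %>%
      ungroup() %>%
      mutate(.chain = paste(.data$.chain, .data$.chain2, sep = ".")) %>%
      select(-".chain2")
  }
  m <- m %>%
    group_by(.data$line_id, .data$chrom, .data$.chain) %>%
    mutate(.size = n()) %>%
    ungroup() %>%
    mutate(cluster_id = if_else(
      .data$.size >= 2L,
      paste(.data$line_id, .data$chrom, .data$.chain, sep = ":"),
      NA_character_
    ))

  clustered <- filter(m, !is.na(.data$cluster_id))
  clusters <- if (nrow(clustered) == 0) {
    tibble(cluster_id = character(), line_id = character(),
           chrom = character(), size = integer(), span_bp = integer(),
           start = integer(), end = integer())
  } else {
    clustered %>%
      group_by(.data$cluster_id, .data$line_id, .data$chrom) %>%
      summarise(
        size = n(), span_bp = max(.data$pos) - min(.data$pos),
        start = min(.data$pos), end = max(.data$pos), .groups = "drop"
      )
  }

  events <- m %>%
    group_by(.data$line_id) %>%
    summarise(
      n_raw = n(),
      n_clusters = dplyr::n_distinct(.data$cluster_id, na.rm = TRUE),
      n_events = sum(is.na(.data$cluster_id)) +
        dplyr::n_distinct(.data$cluster_id, na.rm = TRUE),
      .groups = "drop"
    )

  structure(
    list(members = select(m, -".chain", -".size"), clusters = clusters,
         events = events),
    class = "mnm_result"
  )
}

# greedy left-to-right strict grouping: start a new group when the span
# from the group's first member would exceed the window
.strict_split <- function(pos, window) {
  g <- integer(length(pos)); gi <- 1L; anchor <- pos[1]
  for (i in seq_along(pos)) {
    if (pos[i] - anchor > window) { gi <- gi + 1L; anchor <- pos[i] }
    g[i] <- gi
  }
  g
}

#' @export
print.mnm_result <- function(x, ...) {
  cat(sprintf("<mnm_result> %d cluster(s) among %d mutation(s); %d corrected event(s)\n",
              nrow(x$clusters), nrow(x$members), sum(x$events$n_events)))
  invisible(x)
}

#' Chance probability of a multinucleotide cluster
#'
#' Birthday-type approximation for the probability that at least one pair
#' among `m` uniformly placed mutations in `n` callable sites lies within
#' `window` bp:
#' `P = 1 - prod_{k=1}^{m-1} (1 - 2 * window * k / n)`, clipped to
#' `[0, 1]`. `m <= 1` gives 0.
#'
#' @param m Number of mutations in the line (vectorised).
#' @param n Callable sites.
#' @param window Window in bp (default 50).
#' @return Probability (same length as `m`).
#' @export
#' @examples
#' expected_mnm_probability(2, 27.5e6)   # ~3.6e-6
expected_mnm_probability <- function(m, n, window = 50L) {
  if (any(n <= 0)) abort("n must be > 0")
  if (any(m < 0)) abort("m must be >= 0")
  vapply(seq_along(m), function(i) {
    mi <- m[i]
    ni <- if (length(n) > 1) n[i] else n
    if (mi <= 1) return(0)
    if (ni <= window * mi) abort("n must exceed window * m for the approximation")
    k <- seq_len(mi - 1)
    p <- 1 - prod(1 - 2 * window * k / ni)
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Experiment-level expected MNM probability
#'
#' Mean over lines of [expected_mnm_probability()] evaluated at each
#' line's mutation count and callable sites.
#'
#' @param per_line Tibble with `m` (mutations) and `n` (callable sites).
#' @param window Window in bp (default 50).
#' @return Single probability (per-line mean).
#' @export
expected_mnm_probability_experiment <- function(per_line, window = 50L) {
  mean(expected_mnm_probability(per_line$m, per_line$n, window = window))
}

#' Poisson goodness-of-fit for per-line mutation counts
#'
#' Estimates `lambda` as the mean count, bins counts at k = 0, 1, 2, ...,
#' pools the right tail so every expected bin count is at least 1,
#' computes `chi2 = sum (O - E)^2 / E` with `df = bins - 2` (one degree
#' lost to normalisation, one to the estimated mean), and returns the
#' upper-tail p-value.
#'
#' @param counts Integer vector of per-line counts (>= 5 lines).
#' @return A list of class `"poisson_gof"`: `lambda`, `chi_square`, `df`,
#'   `p_value`, `bins` (tibble `k`, `observed`, `expected`). All-zero
#'   counts give `NA` statistics.
#' @export
poisson_gof <- function(counts) {
  if (length(counts) < 5) abort("need at least 5 lines for the Poisson GOF test")
  if (any(counts < 0)) abort("counts must be >= 0")
  lambda <- mean(counts)
  n <- length(counts)
  if (lambda == 0) {
    return(structure(
      list(lambda = 0, chi_square = NA_real_, df = NA_integer_,
           p_value = NA_real_,
           bins = tibble(k = "0", observed = n, expected = n)),
      class = "poisson_gof"
    ))
  }
  kmax <- max(counts)
  probs <- stats::dpois(0:kmax, lambda)
  probs <- c(probs, 1 - sum(probs))           # right tail > kmax
  expected <- n * probs
  observed <- c(tabulate(counts + 1L, nbins = kmax + 1L), 0L)
  # pool the right tail until every expected bin >= 1
  while (length(expected) > 2 && tail(expected, 1) < 1) {
    k <- length(expected)
    expected[k - 1] <- expected[k - 1] + expected[k]
    observed[k - 1] <- observed[k - 1] + observed[k]
    expected <- expected[-k]; observed <- observed[-k]
  }
  labels <- as.character(seq_along(expected) - 1L)
  labels[length(labels)] <- paste0(">=", length(labels) - 1L)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(expected) - 2L
  p <- if (df >= 1) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  structure(
    list(lambda = lambda, chi_square = chi2, df = df, p_value = p,
         bins = tibble(k = labels, observed = observed, expected = expected)),
    class = "poisson_gof"
  )
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf("<poisson_gof> lambda = %.3g, chi2 = %.3g, df = %s, P = %.3g\n",
              x$lambda, x$chi_square, format(x$df), x$p_value))
  invisible(x)
}
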