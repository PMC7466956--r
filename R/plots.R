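# ggplot2 displays for the main result types.

#' Plot the six-class substitution spectrum
#'
#' @param object A [spectrum_counts()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot spectrum_counts
autoplot.spectrum_counts <- function(object, ...) {
  labels <- c(
    AT_to_GC_ts = "A:T→G:C (ts)", AT_to_CG_tv = "A:T→C:G (tv)",
    AT_to_TA_tv = "A:T→T:A (tv)", GC_to_AT_ts = "G:C→A:T (ts)",
    GC_to_TA_tv = "G:C→T:A (tv)", GC_to_CG_tv = "G:C→C:G (tv)"
  )
  df <- mutate(as_tibble(object),
               class = factor(labels[.data$class], levels = unname(labels)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count,
                                   fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(ts = "#3B6FB6", tv = "#C84C4C"),
                               name = NULL,
                               labels = c("transition", "transversion")) +
    ggplot2::labs(x = NULL, y = "substitutions",
                  title = "Base-substitution spectrum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Per-line mutation counts against the fitted Poisson expectation
#'
#' Reproduces the classic MA-study histogram: bars are the number of
#' lines carrying k mutations, points the Poisson fit at the estimated
#' mean.
#'
#' @param counts Integer vector of per-line counts.
#' @param gof Optional [poisson_gof()] result (recomputed if `NULL`).
#' @return A ggplot.
#' @export
plot_per_line_counts <- function(counts, gof = NULL) {
  if (is.null(gof)) gof <- poisson_gof(counts)
  obs <- tibble(k = 0:max(counts),
                n_lines = tabulate(counts + 1L, nbins = max(counts) + 1L))
  fit <- mutate(obs,
                expected = length(counts) * stats::dpois(.data$k, gof$lambda))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$k, y = .data$n_lines)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_point(data = fit,
                        ggplot2::aes(y = .data$expected), colour = "red",
                        shape = 15, size = 2.5) +
    ggplot2::labs(
      x = "mutations per line", y = "MA lines",
      title = "Per-line mutation counts vs Poisson fit",
      subtitle = sprintf("chi-square = %.2f, P = %.3g",
                         gof$chi_square, gof$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Indel size distribution by SSR context
#'
#' @param mutations A mutation tibble with `in_ssr` set.
#' @return A ggplot.
#' @export
plot_indel_sizes <- function(mutations) {
  ind <- filter(mutations, .data$mclass %in% c("insertion", "deletion"))
  df <- mutate(
    ind,
    signed = if_else(.data$mclass == "insertion",
                     .data$indel_length, -.data$indel_length),
    context = if_else(.data$in_ssr %in% TRUE, "in SSR", "outside SSR")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed, fill = .data$context)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "indel size (bp; deletions negative)", y = "events",
                  fill = NULL, title = "Indel size distribution") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
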