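#' Plot TE class coverage along chromosomes
#'
#' Window-coverage landscape (one panel per chromosome, one line per TE
#' class) from [window_coverage()] output.
#'
#' @param coverage Tibble from [window_coverage()].
#' @return A ggplot object.
#' @export
plot_te_landscape <- function(coverage) {
  ggplot2::ggplot(coverage, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = 100 * .data$coverage,
    colour = .data$te_class
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "Position (Mb)", y = "Coverage (% of window)",
                  colour = "TE class") +
    ggplot2::theme_minimal()
}

#' Plot cluster mean stage profiles
#'
#' Centroid z-score profile per expression cluster, ordered by peak
#' stage.
#'
#' @param x A `te_clustering` from [lloyd_kmeans()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_clustering <- function(x, ...) {
  centers <- as_tibble(x$centers, rownames = NULL) |>
    mutate(cluster = factor(row_number())) |>
    tidyr::pivot_longer(-"cluster", names_to = "stage", values_to = "z")
  centers$stage <- factor(centers$stage, levels = colnames(x$centers))
  ggplot2::ggplot(centers, ggplot2::aes(
    x = .data$stage, y = .data$z, group = .data$cluster,
    colour = .data$cluster
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Developmental stage", y = "Mean z-score",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Plot family age against copy number
#'
#' Scatter of median terminal-branch age versus copy number (log10) per
#' family, coloured by TE class.
#'
#' @param ages Family-age tibble from [estimate_family_ages()].
#' @param families Tibble with `family`, `copy_number` and optionally
#'   `te_class`.
#' @return A ggplot object.
#' @export
plot_family_ages <- function(ages, families) {
  df <- ages |>
    filter(.data$status == "ok") |>
    left_join(distinct(families, .data$family, .keep_all = TRUE),
              by = "family")
  aes <- if ("te_class" %in% names(df)) {
    ggplot2::aes(x = .data$copy_number, y = .data$median_terminal_branch,
                 colour = .data$te_class)
  } else {
    ggplot2::aes(x = .data$copy_number, y = .data$median_terminal_branch)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Copy number (loci)",
                  y = "Median terminal branch (subst./site)",
                  colour = "TE class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
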