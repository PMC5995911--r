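#' Heatmap of an occupancy matrix
#'
#' @param object An `occupancy_matrix`.
#' @param ... Unused.
#' @return A ggplot: anchors (rows, ordered as in the matrix) by bp offset,
#'   filled by normalized occupancy.
#' @export
autoplot.occupancy_matrix <- function(object, ...) {
  df <- tidy(object) |>
    mutate(gene_id = factor(.data$gene_id, levels = rev(rownames(object))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$gene_id,
                                   fill = .data$occupancy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "distance from anchor (bp)", y = NULL,
                  fill = "occupancy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Average-profile line plot
#'
#' @param profile Tibble from [average_profile()], optionally with a
#'   `condition` column (one line per condition).
#' @return A ggplot of mean normalized occupancy against bp offset.
#' @export
plot_profile <- function(profile) {
  aes <- if ("condition" %in% names(profile)) {
    ggplot2::aes(x = .data$offset, y = .data$occupancy,
                 colour = .data$condition)
  } else {
    ggplot2::aes(x = .data$offset, y = .data$occupancy)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from TSS (bp)",
                  y = "mean normalized occupancy") +
    ggplot2::theme_minimal()
}

#' Running-sum enrichment plot
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot of the running enrichment score with hit positions
#'   marked along the rank axis.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f, NES = %.3f, p = %.3g",
                                     object$es, object$nes, object$pvalue)) +
    ggplot2::theme_minimal()
}

#' Stacked category fractions from an AP-staining categorization
#'
#' @param ap Result of [ap_categorize()].
#' @return A ggplot stacked-bar chart of low/intermediate/high fractions
#'   per sample.
#' @export
plot_ap_fractions <- function(ap) {
  df <- ap$fractions |>
    mutate(category = factor(.data$category,
                             levels = c("low", "intermediate", "high")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(low = "#d7301f",
                                          intermediate = "#fdcc8a",
                                          high = "#2b8cbe")) +
    ggplot2::labs(x = NULL, y = "fraction of colonies") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
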