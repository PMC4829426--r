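#' GC-coverage bubble plot of taxonomically binned contigs
#'
#' Draws contigs as bubbles in the plane spanned by GC content and mean
#' coverage, radius proportional to contig length and colour by taxon bin —
#' the standard visual check that consensus bins form coherent clusters.
#'
#' @param contigs Data frame from [gc_coverage_filter()] (needs `gc`,
#'   `coverage`, `radius`), optionally with a `taxobin` column.
#' @return A ggplot object.
#' @export
plot_gc_coverage <- function(contigs) {
  contigs <- as_tibble(contigs)
  p <- ggplot2::ggplot(contigs,
                       ggplot2::aes(x = .data$gc, y = .data$coverage)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "GC content (%)", y = "Mean coverage",
                  size = "Contig length") +
    ggplot2::theme_minimal()
  if ("taxobin" %in% names(contigs)) {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$radius,
                                         colour = .data$taxobin),
                            alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$radius), alpha = 0.7)
  }
}

#' Plot a gene-frequency profile
#'
#' Bar panel per scope showing each family's coverage-weighted gene
#' frequency.
#'
#' @param object A `frequency_profile` from [family_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.frequency_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$family, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~scope, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Gene frequency (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot clade abundances against an environmental driver series
#'
#' Clade abundances on a log axis over samples, with one environment
#' variable overlaid (rescaled) for visual comparison of bloom timing.
#'
#' @param clades Tibble of clade abundance columns.
#' @param env Environmental table with `sample_id` and the driver column.
#' @param driver Name of the environmental variable to overlay.
#'   Default `"chlorophyll_a"`.
#' @return A ggplot object.
#' @export
plot_clade_series <- function(clades, env, driver = "chlorophyll_a") {
  d <- dplyr::bind_cols(select(as_tibble(env), "sample_id"),
                        as_tibble(clades)) |>
    mutate(t = row_number()) |>
    tidyr::pivot_longer(-c("sample_id", "t"), names_to = "clade",
                        values_to = "abundance")
  drv <- tibble(t = seq_len(nrow(env)), value = env[[driver]])
  drv$value <- drv$value / max(drv$value) * max(d$abundance)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$abundance,
                                  colour = .data$clade)) +
    ggplot2::geom_line() +
    ggplot2::geom_area(data = drv,
                       ggplot2::aes(x = .data$t, y = .data$value),
                       inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Sample", y = "Abundance",
                  caption = paste("shaded:", driver, "(rescaled)")) +
    ggplot2::theme_minimal()
}
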