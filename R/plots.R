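utils::globalVariables(c("length_a", "length_b", "population", "value"))

#' Scatterplot of shared-TR total lengths
#'
#' Total array length of each homologous pair's member A against member B.
#' Requires ggplot2.
#'
#' @param pairs Output of [reciprocal_homologs()] (or a
#'   [shared_length_table()]).
#' @return A ggplot object.
#' @export
plot_shared_lengths <- function(pairs) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tab <- if (all(c("length_a", "length_b") %in% names(pairs))) pairs else
    shared_length_table(pairs)
  ggplot2::ggplot(tab, ggplot2::aes(x = length_a, y = length_b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "TR length, assembly A (bp)",
                  y = "TR length, assembly B (bp)") +
    ggplot2::theme_minimal()
}

#' Violin plot of observed heterozygosity per population
#'
#' @param pop_summary Long table from [population_summary()].
#' @param statistic Which statistic to plot (default `"obs_het"`).
#' @return A ggplot object.
#' @export
plot_population_het <- function(pop_summary, statistic = "obs_het") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tab <- pop_summary[pop_summary$statistic == statistic, , drop = FALSE]
  ggplot2::ggplot(tab, ggplot2::aes(x = population, y = value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.6) +
    ggplot2::labs(x = "Population", y = statistic) +
    ggplot2::theme_minimal()
}
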