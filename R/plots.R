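# ggplot2 views of the main result types.

#' Heatmap of relative allele frequencies across samples
#'
#' One tile per sample x allele, shaded by relative read frequency --
#' the at-a-glance view of which samples lost the transposon allele and
#' which gained footprints.
#'
#' @param freqs One or more row-bound `frequency_table`s.
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(freqs) {
  ggplot2::ggplot(as_tibble(freqs),
                  ggplot2::aes(x = .data$allele, y = .data$sample_id,
                               fill = .data$freq)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "frequency") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.mismatch_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                               fill = .data$mismatches)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mismatches") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' @export
autoplot.genotype_call <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$allele, y = .data$dosage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "allele dosage") +
    ggplot2::theme_minimal()
}

#' Dot plot of bolter vs control phenotypes
#'
#' @param phenotypes Phenotype table with a `group` column.
#' @param trait Trait column to plot.
#' @return A ggplot object.
#' @export
plot_phenotypes <- function(phenotypes, trait = "total_inflorescences") {
  ggplot2::ggplot(as_tibble(phenotypes),
                  ggplot2::aes(x = .data$group, y = .data[[trait]],
                               color = .data$group)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 2, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          color = "black") +
    ggplot2::labs(x = NULL, y = trait) +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
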