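# ggplot2 views of the main result types.

#' Bar plot of isoform classification results
#'
#' @param classified Output of [classify_isoforms()].
#' @return A ggplot object.
#' @export
plot_isoform_classes <- function(classified) {
  summarize_classes(classified) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "isoforms",
                  title = "Isoform classification vs reference") +
    ggplot2::theme_minimal()
}

#' Isoforms-per-gene histogram
#'
#' @param as_genes Output of [detect_as_genes()].
#' @return A ggplot object.
#' @export
plot_isoform_histogram <- function(as_genes) {
  ggplot2::ggplot(as_genes, ggplot2::aes(x = .data$n_isoforms)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "isoforms per gene", y = "genes") +
    ggplot2::theme_minimal()
}

#' Entropy distributions by subgenome or feature kind
#'
#' @param entropy Tibble from [shannon_entropy()] with an added grouping
#'   column.
#' @param group Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_entropy <- function(entropy, group = "kind") {
  ggplot2::ggplot(entropy,
                  ggplot2::aes(x = .data$entropy,
                               colour = .data[[group]])) +
    ggplot2::geom_density(na.rm = TRUE) +
    ggplot2::labs(x = "Shannon entropy (bits)", y = "density") +
    ggplot2::theme_minimal()
}

#' Substitution-type spectrum of editing sites
#'
#' @param typed Output of [substitution_type()].
#' @return A ggplot object.
#' @export
plot_substitution_spectrum <- function(typed) {
  typed %>%
    count(.data$type) %>%
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$type, -.data$n),
                                 y = .data$n)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "editing sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the contrast battery of a subgenome report
#'
#' @param object A `subgenome_report`.
#' @param ... Unused.
#' @return A ggplot object showing -log10 adjusted p per contrast.
#' @export
autoplot.subgenome_report <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$event,
                                 y = -log10(.data$p_adjust),
                                 fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 BH-adjusted p") +
    ggplot2::theme_minimal()
}
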