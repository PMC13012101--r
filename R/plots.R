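#' Influence quadrant plot
#'
#' Heat-diffusion influence against personalized-PageRank mass, with the
#' median split lines and quadrant categories.
#'
#' @param influence Tibble from [influence_scores()] /
#'   [classify_quadrants()].
#' @param label Label points with gene symbols (default TRUE).
#' @return A ggplot object.
#' @export
plot_influence_quadrants <- function(influence, label = TRUE) {
  p <- ggplot2::ggplot(influence,
                       ggplot2::aes(x = .data$ppr, y = .data$heat,
                                    colour = .data$category)) +
    ggplot2::geom_vline(xintercept = median(influence$ppr),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(yintercept = median(influence$heat),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "personalized PageRank", y = "heat-diffusion influence",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$gene),
                                size = 2.5, vjust = -0.8, show.legend = FALSE)
  }
  p
}

#' PAS by group boxplot
#'
#' @param pas PAS tibble from [compute_pas()] joined with a `group` column
#'   (e.g. via the sample metadata).
#' @return A ggplot object.
#' @export
plot_pas_groups <- function(pas) {
  if (!"group" %in% names(pas)) abort("`pas` needs a `group` column.")
  ggplot2::ggplot(pas, ggplot2::aes(x = .data$group, y = .data$pas,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "PAS") +
    ggplot2::theme_minimal()
}

#' Dose-response trajectories of delta-PAS
#'
#' @param deltas Tibble from [signature_delta_pas()].
#' @param drugs Optional drug subset.
#' @return A ggplot object: delta-PAS vs log10 concentration, one panel per
#'   cell line.
#' @export
plot_dose_response <- function(deltas, drugs = NULL) {
  if (!is.null(drugs)) deltas <- dplyr::filter(deltas, .data$drug %in% drugs)
  ggplot2::ggplot(deltas,
                  ggplot2::aes(x = log10(.data$concentration),
                               y = .data$delta_pas,
                               colour = .data$drug, group = .data$drug)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_line)) +
    ggplot2::labs(x = "log10 concentration", y = expression(Delta * "PAS"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Partial-correlation heatmap of a GGM fit
#'
#' @param object A `ggm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ggm_fit <- function(object, ...) {
  df <- tidyr::expand_grid(gene1 = object$genes, gene2 = object$genes)
  df$pcor <- as.vector(t(object$pcor))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene1, y = .data$gene2,
                                   fill = .data$pcor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "pcor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Perturbation effect-size ladder plot
#'
#' Cohen's d of the PAS shift against the perturbation factor (log2 x-axis),
#' one line per query gene.
#'
#' @param outcomes The `outcomes` tibble from [perturbation_screen()].
#' @return A ggplot object.
#' @export
plot_perturbation_ladder <- function(outcomes) {
  ggplot2::ggplot(outcomes,
                  ggplot2::aes(x = log2(.data$factor), y = .data$cohen_d,
                               colour = .data$query)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "log2 perturbation factor", y = "Cohen's d (PAS shift)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
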