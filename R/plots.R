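## ggplot2 views of the main result types. These are thin presentation
## layers over the tables the analysis functions return.

#' Violin plot of a signature across samples
#'
#' Distribution of `log2(normalized + 1)` over signature genes per sample,
#' faceted by model with stages side by side — the standard view for a
#' proliferation or androgen-response shutdown after castration.
#'
#' @inheritParams signature_summary
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_signature_violin <- function(experiment, gene_set, normalized = NULL,
                                  title = "Signature expression") {
  norm <- resolve_normalized(experiment, normalized)
  present <- intersect(gene_set, norm$gene)
  if (length(present) < 2) {
    abort("Signature has fewer than 2 genes in the experiment.",
          class = "dormantx_geneset_error")
  }
  meta <- experiment$sample_meta
  long <- norm[norm$gene %in% present, ] |>
    tidyr::pivot_longer(-"gene", names_to = "sample",
                        values_to = "normalized") |>
    dplyr::left_join(meta, by = "sample") |>
    dplyr::mutate(log2_expr = log2(.data$normalized + 1))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$log2_expr,
                                     fill = .data$stage)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::facet_wrap(~model, nrow = 1) +
    ggplot2::labs(title = title, x = NULL,
                  y = "log2(normalized count + 1)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' @describeIn select_discriminative_features Bar chart of normalized
#'   importances for the selected genes.
#' @param object A `feature_ranking`.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_ranking <- function(object, ...) {
  sel <- dplyr::filter(object$ranking, .data$selected)
  ggplot2::ggplot(sel, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalized importance",
                  title = sprintf("Top %d discriminative genes", nrow(sel))) +
    ggplot2::theme_bw()
}

#' Heatmap of clustered genes and samples
#'
#' Tile heatmap of `log2(normalized + 1)` with rows and columns arranged by
#' the Ward.D2/Canberra leaf orders from [cluster_heatmap()].
#'
#' @inheritParams cluster_heatmap
#' @param clustering Optional precomputed [cluster_heatmap()] result.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(experiment, genes = NULL,
                                    clustering = NULL, normalized = NULL) {
  norm <- resolve_normalized(experiment, normalized)
  clustering <- clustering %||%
    cluster_heatmap(experiment, genes = genes, normalized = normalized)
  if (!is.null(genes)) norm <- norm[norm$gene %in% genes, ]
  long <- norm |>
    tidyr::pivot_longer(-"gene", names_to = "sample",
                        values_to = "normalized") |>
    dplyr::mutate(
      gene = factor(.data$gene, levels = clustering$gene_order),
      sample = factor(.data$sample, levels = clustering$sample_order),
      log2_expr = log2(.data$normalized + 1))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$gene,
                                     fill = .data$log2_expr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2(norm+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}
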