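#' Motif significance scatter
#'
#' Scatter of motif groups on the two enrichment axes (-log10 p for
#' V-gene and expansion enrichment), dot radius proportional to the final
#' score and colour by motif kind; dashed lines mark the significance
#' level, so significant groups occupy the upper-right quadrant.
#'
#' @param motifs Scored motif tibble (see [score_motif_groups()]).
#' @param alpha Significance level for the quadrant lines.
#' @return A ggplot object.
#' @export
plot_motif_scatter <- function(motifs, alpha = 0.05) {
  ggplot2::ggplot(
    motifs,
    ggplot2::aes(x = -log10(.data$vgene_enrichment_p),
                 y = -log10(.data$expansion_enrichment_p),
                 size = .data$final_score, colour = .data$kind)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(global = "#c0392b", local = "#2980b9", single = "grey60")
    ) +
    ggplot2::labs(x = "-log10 P (V-gene enrichment)",
                  y = "-log10 P (expansion enrichment)",
                  size = "final score", colour = "motif kind") +
    ggplot2::theme_minimal()
}

#' J-gene sharing heatmap
#'
#' Clonotype-by-subject tile map of the J-sharing groups, tile intensity
#' proportional to isolate count and faceted by group.
#'
#' @param groups Output of [jgene_sharing_groups()].
#' @return A ggplot object.
#' @export
plot_jgene_heatmap <- function(groups) {
  mat <- jgene_sharing_matrix(groups)
  ggplot2::ggplot(mat, ggplot2::aes(x = .data$donor, y = .data$clonotype_id,
                                    fill = .data$n_isolates)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_gradient(low = "#fde0dd", high = "#7a0177") +
    ggplot2::labs(x = "subject", y = "clonotype", fill = "isolates") +
    ggplot2::theme_minimal()
}

#' Phenotype bit heatmap
#'
#' Cells-by-marker presence/absence map, cells ordered by donor.
#'
#' @param cells Annotated cell tibble carrying 0/1 marker columns.
#' @param markers Marker columns to show (default: full panel present in
#'   the table).
#' @return A ggplot object.
#' @export
plot_phenotype_heatmap <- function(cells, markers = NULL) {
  if (is.null(markers)) {
    markers <- intersect(phenotype_panel()$marker, names(cells))
  }
  long <- cells |>
    arrange(donor) |>
    mutate(cell = factor(well_id, levels = unique(well_id))) |>
    tidyr::pivot_longer(dplyr::all_of(markers), names_to = "marker",
                        values_to = "bit")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$marker,
                                     fill = factor(.data$bit))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "#c0392b"),
                               name = "transcript") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "cell", y = NULL)
}

#' Expanded-cell percentage bars per tetramer
#'
#' @param skew_tests The `tests` tibble from [expansion_skew_tests()] or
#'   the `skew_tests` component of a pipeline result.
#' @return A ggplot object.
#' @export
plot_expansion_contingency <- function(skew_tests) {
  cols <- names(skew_tests)
  gexp <- grep("_expanded$", cols, value = TRUE)
  gtot <- grep("_total$", cols, value = TRUE)
  groups <- sub("_expanded$", "", gexp)
  long <- purrr::map_dfr(seq_along(groups), function(i) {
    tibble(tetramer = skew_tests$tetramer, group = groups[[i]],
           pct = 100 * skew_tests[[gexp[i]]] / skew_tests[[gtot[i]]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tetramer, y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% cells expanded") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.tcr_bky <- function(object, ...) {
  df <- tidy(object) |>
    arrange(p_value) |>
    mutate(rank = row_number())
  m <- nrow(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$p_value,
                                   colour = .data$discovery)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$stage1_threshold / max(m, 1L),
                         intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = (object$stage2_level %||% 0) / max(m, 1L),
                         intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "rank", y = "p-value",
                  colour = "discovery") +
    ggplot2::theme_minimal()
}
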