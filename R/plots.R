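#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ordination plot with group dispersion ellipses
#'
#' @param object An `ambin_cap` or `ambin_pcoa`.
#' @param groups Optional named vector mapping sample id to treatment
#'   (required for PCoA; CAP results carry their own).
#' @param ellipse_level Coverage of the per-group normal ellipse.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ambin_ordination <- function(object, groups = NULL,
                                      ellipse_level = 0.95, ...) {
  pts <- object$points
  axes <- setdiff(names(pts), c("sample_id", "treatment"))[1:2]
  if (!("treatment" %in% names(pts))) {
    assert_that(!is.null(groups), "supply `groups` for PCoA plots")
    pts$treatment <- unname(groups[pts$sample_id])
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                         colour = .data$treatment)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "Treatment")
  tab <- table(pts$treatment)
  if (all(tab >= 3))
    p <- p + ggplot2::stat_ellipse(level = ellipse_level, type = "norm")
  p
}

#' Fold-change plot of differentially abundant OTUs
#'
#' One panel per contrast: significant OTUs ordered by log2 fold change,
#' with infinite fold changes pinned at the panel edge.
#'
#' @param object An `ambin_da` result tibble.
#' @param alpha Significance level for inclusion.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ambin_da <- function(object, alpha = 0.05, ...) {
  res <- tibble::as_tibble(object) |>
    dplyr::filter(.data$status %in% c("tested", "infinite_fc"),
                  !is.na(.data$padj), .data$pvalue < alpha,
                  .data$padj < alpha) |>
    dplyr::mutate(contrast = paste(.data$contrast_a, "vs", .data$contrast_b))
  if (nrow(res) == 0)
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No differentially abundant OTUs"))
  cap_val <- max(abs(res$log2fc[is.finite(res$log2fc)]), 1) + 1
  res <- res |>
    dplyr::mutate(lfc_plot = pmin(pmax(.data$log2fc, -cap_val), cap_val),
                  infinite = !is.finite(.data$log2fc))
  ggplot2::ggplot(res, ggplot2::aes(.data$lfc_plot,
                                    stats::reorder(.data$otu_id, .data$lfc_plot),
                                    shape = .data$infinite)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~contrast, scales = "free_y") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8),
                                labels = c("finite", "+/-INF"),
                                name = NULL) +
    ggplot2::labs(x = "log2 fold change", y = NULL) +
    ggplot2::theme_minimal()
}

#' Alpha-diversity box plots by treatment
#'
#' @param diversity Tibble from [alpha_diversity()].
#' @param design Sample design tibble.
#' @param indices Which index columns to show.
#' @return A ggplot.
#' @export
plot_alpha_diversity <- function(diversity, design,
                                 indices = c("shannon", "inv_simpson")) {
  dat <- diversity |>
    dplyr::left_join(design, by = "sample_id") |>
    tidyr::pivot_longer(dplyr::all_of(indices), names_to = "index") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(dat, ggplot2::aes(.data$treatment, .data$value,
                                    fill = .data$treatment)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL)
}
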